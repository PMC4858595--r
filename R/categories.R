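#' Canonical cost-category scheme
#'
#' The service-use and substance-use categories recorded per participant,
#' each assigned to a sector: `health_care`, or one of the four
#' intersectoral cost-and-benefit (ICB) sectors (`education`,
#' `labor_social_security`, `household_leisure`, `criminal_justice`), or
#' `substance_use`.  Substance use is deliberately kept outside the ICB
#' sectors so that the "without substance costs" sensitivity scenario is a
#' column toggle rather than a re-costing.
#'
#' Alcohol purchases are intentionally absent: alcohol consumption is the
#' effect measure, so valuing it as a cost would double count.
#'
#' @return A data frame with columns `category`, `sector` and `kind`
#'   (`count`, `hours` or `days`; `days` categories are bounded by the
#'   recall window).
#' @export
cost_categories <- function() {
  data.frame(
    category = c(
      "gp_contacts", "emergency_visits", "hospital_days", "ambulance_rides",
      "mental_health_contacts",
      "school_absence_hours", "attendance_officer_contacts",
      "work_absence_hours",
      "household_hours_missed", "other_activity_hours_missed",
      "youth_family_center_contacts", "family_care_contacts",
      "police_contacts", "youth_police_contacts", "court_proceedings",
      "child_protection_contacts", "child_health_protection_contacts",
      "cigarette_packs", "soft_drug_units", "hard_drug_units"
    ),
    sector = c(
      rep("health_care", 5),
      rep("education", 2),
      "labor_social_security",
      rep("household_leisure", 4),
      rep("criminal_justice", 5),
      rep("substance_use", 3)
    ),
    kind = c(
      "count", "count", "days", "count", "count",
      "hours", "count",
      "hours",
      "hours", "hours", "count", "count",
      "count", "count", "count", "count", "count",
      "count", "count", "count"
    ),
    stringsAsFactors = FALSE
  )
}

#' Sectors that make up the intersectoral costs and benefits
#' @return Character vector of ICB sector names.
#' @export
icb_sectors <- function() {
  c("education", "labor_social_security", "household_leisure",
    "criminal_justice")
}

all_sectors <- function() {
  c("health_care", icb_sectors(), "substance_use")
}
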