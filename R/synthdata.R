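# Synthetic cluster-RCT generator with known ground truth.
#
# Emulates a two-arm school-randomized prevention trial: baseline
# demographic imbalance between arms, school-level random intercepts on the
# drinking outcomes (targeting a requested intraclass correlation),
# zero-inflated right-skewed service-use volumes, deliberate
# "unrealistic answer" contamination, and heavy covariate-dependent
# dropout at follow-up.

#' Describe a synthetic trial scenario
#'
#' Bundles every knob of the generator with validation.  The defaults are
#' calibrated to a Dutch school-based alcohol-prevention trial: 34 schools
#' (~78 adolescents each, about 2650 at baseline), intraclass correlations
#' of 0.01 for weekly alcohol use and 0.06 for binge-drinking occasions, a
#' secular increase of 1.51 glasses/week (0.33 binge occasions) between
#' baseline and 4-month follow-up, incremental intervention effects of
#' 0.73 glasses/week and 0.49 occasions, roughly 3.4% systematic
#' unrealistic answering, and ~70% attrition at follow-up.
#'
#' @param n_clusters_per_arm Schools per arm (balanced design).
#' @param cluster_size_mean Participants per school; every school is
#'   generated at exactly this size.
#' @param icc_weekly,icc_binge Target intraclass correlation of the change
#'   score in each outcome, in `[0, 1)`.
#' @param arm_effect_weekly,arm_effect_binge Mean extra reduction achieved
#'   by the intervention arm (glasses/week, binge occasions per 30 days).
#' @param secular_drift,secular_drift_binge Increase experienced by
#'   everyone between T0 and T1 (so control-arm change scores center at
#'   minus this value).
#' @param sd_change_weekly,sd_change_binge Total standard deviation of the
#'   latent change score (between- plus within-school components).
#' @param weekly_t0_model,binge_t0_model Baseline outcome models:
#'   lists with `p_zero` (never-drinker probability), `mu` (positive-part
#'   mean) and `dispersion` (squared coefficient of variation for the
#'   log-normal weekly model; negative-binomial size for binge counts).
#' @param volume_models Named list, one entry per cost category, each a
#'   list with `p_zero`, `mu` (positive-part mean), `dispersion` and
#'   `type` (`"count"` for zero-inflated negative binomial, `"hours"` for
#'   zero-inflated log-normal).  Defaults from [default_volume_models()].
#' @param contamination_rate Fraction of participants who systematically
#'   fill in unrealistic answers.
#' @param contamination_magnitude Multiplier applied to the plausibility
#'   limit when injecting unrealistic values (must exceed 1).
#' @param dropout_rate Marginal probability of missing the follow-up
#'   measurement, in `[0, 1)`.
#' @param dropout_covariate_weights Named numeric vector of log-odds
#'   contributions per unit of (centered) covariate; recognised names:
#'   `age`, `male`, `female`, `high_education`, `religious`, `dutch`,
#'   `weekly_glasses_t0`, `binge_t0`.  Non-zero weights make missingness
#'   not-at-random by construction.
#' @param baseline_imbalance Named numeric vector of prevalence offsets
#'   added to the intervention arm for `female`, `high_education`,
#'   `religious` and `dutch`.
#' @param missing_cost_t0_rate,missing_cost_t1_rate Probability of not
#'   answering a single cost question at each wave.
#' @param seed Integer scenario seed; all stage streams derive from it.
#' @return An object of class `trial_scenario`.
#' @seealso [generate_trial()]
#' @export
trial_scenario <- function(n_clusters_per_arm = 17,
                           cluster_size_mean = 78,
                           icc_weekly = 0.01,
                           icc_binge = 0.06,
                           arm_effect_weekly = 0.73,
                           arm_effect_binge = 0.49,
                           secular_drift = 1.51,
                           secular_drift_binge = 0.33,
                           sd_change_weekly = 5,
                           sd_change_binge = 2.5,
                           weekly_t0_model = list(p_zero = 0.27, mu = 5.3,
                                                  dispersion = 1.8),
                           binge_t0_model = list(p_zero = 0.49, mu = 4.3,
                                                 dispersion = 1.2),
                           volume_models = default_volume_models(),
                           contamination_rate = 0.034,
                           contamination_magnitude = 50,
                           dropout_rate = 0.70,
                           dropout_covariate_weights = c(age = 0.15,
                                                         male = 0.30),
                           baseline_imbalance = c(female = 0.14,
                                                  high_education = 0.17,
                                                  religious = 0.06,
                                                  dutch = 0.01),
                           missing_cost_t0_rate = 0.025,
                           missing_cost_t1_rate = 0.053,
                           seed = 1L) {
  if (!is.numeric(n_clusters_per_arm) || n_clusters_per_arm < 1) {
    stop("invalid scenario parameter 'n_clusters_per_arm': must be >= 1")
  }
  if (!is.numeric(cluster_size_mean) || cluster_size_mean < 2) {
    stop("invalid scenario parameter 'cluster_size_mean': must be >= 2")
  }
  check_fraction(icc_weekly, "icc_weekly")
  check_fraction(icc_binge, "icc_binge")
  check_fraction(contamination_rate, "contamination_rate")
  check_fraction(dropout_rate, "dropout_rate")
  check_fraction(missing_cost_t0_rate, "missing_cost_t0_rate")
  check_fraction(missing_cost_t1_rate, "missing_cost_t1_rate")
  check_nonneg(sd_change_weekly, "sd_change_weekly")
  check_nonneg(sd_change_binge, "sd_change_binge")
  if (contamination_magnitude <= 1) {
    stop("invalid scenario parameter 'contamination_magnitude': must be > 1")
  }
  for (nm in c("weekly_t0_model", "binge_t0_model")) {
    m <- get(nm)
    check_fraction(m$p_zero, paste0(nm, "$p_zero"), allow_one = TRUE)
    if (!is.finite(m$mu) || m$mu <= 0) {
      stop(sprintf("invalid scenario parameter '%s$mu': must be finite and > 0", nm))
    }
    if (!is.finite(m$dispersion) || m$dispersion <= 0) {
      stop(sprintf("invalid scenario parameter '%s$dispersion': must be > 0", nm))
    }
  }
  cats <- cost_categories()$category
  missing_models <- setdiff(cats, names(volume_models))
  if (length(missing_models)) {
    stop("invalid scenario parameter 'volume_models': no model for ",
         paste(missing_models, collapse = ", "))
  }
  for (nm in names(volume_models)) {
    m <- volume_models[[nm]]
    check_fraction(m$p_zero, paste0("volume_models$", nm, "$p_zero"),
                   allow_one = TRUE)
    if (!is.finite(m$mu) || m$mu <= 0) {
      stop(sprintf("invalid scenario parameter 'volume_models$%s$mu': must be > 0", nm))
    }
    if (!is.finite(m$dispersion) || m$dispersion <= 0) {
      stop(sprintf("invalid scenario parameter 'volume_models$%s$dispersion': must be > 0", nm))
    }
  }
  bad_w <- setdiff(names(dropout_covariate_weights),
                   c("age", "male", "female", "high_education", "religious",
                     "dutch", "weekly_glasses_t0", "binge_t0"))
  if (length(bad_w)) {
    stop("invalid scenario parameter 'dropout_covariate_weights': unknown covariate ",
         paste(bad_w, collapse = ", "))
  }
  structure(
    list(
      n_clusters_per_arm = as.integer(n_clusters_per_arm),
      cluster_size_mean = as.integer(cluster_size_mean),
      icc_weekly = icc_weekly, icc_binge = icc_binge,
      arm_effect_weekly = arm_effect_weekly,
      arm_effect_binge = arm_effect_binge,
      secular_drift = secular_drift,
      secular_drift_binge = secular_drift_binge,
      sd_change_weekly = sd_change_weekly,
      sd_change_binge = sd_change_binge,
      weekly_t0_model = weekly_t0_model,
      binge_t0_model = binge_t0_model,
      volume_models = volume_models,
      contamination_rate = contamination_rate,
      contamination_magnitude = contamination_magnitude,
      dropout_rate = dropout_rate,
      dropout_covariate_weights = dropout_covariate_weights,
      baseline_imbalance = baseline_imbalance,
      missing_cost_t0_rate = missing_cost_t0_rate,
      missing_cost_t1_rate = missing_cost_t1_rate,
      seed = as.integer(seed)
    ),
    class = "trial_scenario"
  )
}

#' Default zero-inflated volume models
#'
#' Per-category generating models for the service-use and substance-use
#' volumes over a 4-month recall window.  Count-like categories use a
#' zero-inflated negative binomial (positive part shifted by one so the
#' stated `mu` is the positive-part mean); hour-like categories use a
#' zero-inflated log-normal with `dispersion` read as the squared
#' coefficient of variation.  Levels are free calibration choices: rare
#' and expensive events (hospital stays, court proceedings) get high zero
#' probabilities, everyday items (school absence, cigarettes) lower ones.
#'
#' @return Named list of model specifications.
#' @export
default_volume_models <- function() {
  zinb <- function(p_zero, mu, dispersion = 1) {
    list(p_zero = p_zero, mu = mu, dispersion = dispersion, type = "count")
  }
  ziln <- function(p_zero, mu, dispersion = 2) {
    list(p_zero = p_zero, mu = mu, dispersion = dispersion, type = "hours")
  }
  list(
    gp_contacts                      = zinb(0.55, 1.6),
    emergency_visits                 = zinb(0.90, 1.3),
    hospital_days                    = zinb(0.97, 2.5),
    ambulance_rides                  = zinb(0.97, 1.2),
    mental_health_contacts           = zinb(0.85, 4.0),
    school_absence_hours             = ziln(0.45, 10),
    attendance_officer_contacts      = zinb(0.95, 1.5),
    work_absence_hours               = ziln(0.75, 6),
    household_hours_missed           = ziln(0.60, 4),
    other_activity_hours_missed      = ziln(0.60, 5),
    youth_family_center_contacts     = zinb(0.98, 1.5),
    family_care_contacts             = zinb(0.98, 2.0),
    police_contacts                  = zinb(0.92, 1.5),
    youth_police_contacts            = zinb(0.97, 1.3),
    court_proceedings                = zinb(0.985, 1.2),
    child_protection_contacts        = zinb(0.99, 1.2),
    child_health_protection_contacts = zinb(0.99, 1.2),
    cigarette_packs                  = zinb(0.70, 8.0, 1.5),
    soft_drug_units                  = zinb(0.88, 4.0),
    hard_drug_units                  = zinb(0.985, 2.0)
  )
}

# Positive-part draws -------------------------------------------------------

# Zero-inflated NB on {0, 1, 2, ...}: positive part is 1 + NB with mean
# mu - 1 (so the positive-part mean is exactly mu) and size = dispersion.
draw_zinb <- function(n, p_zero, mu, dispersion) {
  out <- numeric(n)
  pos <- stats::runif(n) >= p_zero
  npos <- sum(pos)
  if (npos) {
    shift_mu <- max(mu - 1, 1e-8)
    out[pos] <- 1 + stats::rnbinom(npos, size = dispersion, mu = shift_mu)
  }
  out
}

# Zero-inflated log-normal: dispersion = squared CV of the positive part.
draw_ziln <- function(n, p_zero, mu, dispersion) {
  out <- numeric(n)
  pos <- stats::runif(n) >= p_zero
  npos <- sum(pos)
  if (npos) {
    sdlog <- sqrt(log(1 + dispersion))
    meanlog <- log(mu) - sdlog^2 / 2
    out[pos] <- stats::rlnorm(npos, meanlog, sdlog)
  }
  out
}

religion_levels <- function() c("Catholic", "Protestant", "Muslim", "other", "none")
ethnicity_levels <- function() {
  c("Dutch", "Antillean", "Belgian", "German", "Surinamese", "Moroccan",
    "Turkish", "other")
}

#' Generate a synthetic cluster-randomized trial
#'
#' Draws a full participant table plus a ground-truth record.  Each
#' generation stage (design frame, demographics, outcomes, volumes,
#' questionnaire completeness, contamination, dropout) uses its own RNG
#' stream derived from the scenario seed by a fixed label, so enabling or
#' disabling a later stage never perturbs earlier draws and the output is
#' bit-identical under the same seed.
#'
#' School-level random intercepts are added to the latent change score of
#' each outcome with between/within variances `icc * sd^2` and
#' `(1 - icc) * sd^2`, so the change-score intraclass correlation matches
#' the scenario target in expectation.  Follow-up values are floored at
#' zero (and binge occasions capped at 30), which attenuates the cluster
#' structure and arm effect when much of the sample sits at zero -- a
#' deliberate mirror of real bounded outcomes; convergence checks use
#' scenarios away from the floor.
#'
#' @param scenario A [trial_scenario()].
#' @return A list of class `cea_trial` with elements `participants` (data
#'   frame, one row per adolescent; follow-up columns `NA` for dropouts)
#'   and `truth` (list: true incremental effects, ICCs, expected volume
#'   means per category and arm, contaminated ids, dropout ids).
#' @examples
#' tr <- generate_trial(trial_scenario(n_clusters_per_arm = 2,
#'                                     cluster_size_mean = 10,
#'                                     dropout_rate = 0.3, seed = 7))
#' nrow(tr$participants)
#' @export
generate_trial <- function(scenario) {
  if (!inherits(scenario, "trial_scenario")) {
    stop("'scenario' must be created by trial_scenario()")
  }
  sc <- scenario
  k <- sc$n_clusters_per_arm
  m <- sc$cluster_size_mean
  n <- 2L * k * m

  cluster_ids <- sprintf("S%03d", seq_len(2L * k))
  cluster_arm <- rep(c("intervention", "control"), each = k)
  tab <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    cluster_id = rep(cluster_ids, each = m),
    arm = rep(cluster_arm, each = m),
    stringsAsFactors = FALSE
  )
  is_int <- tab$arm == "intervention"

  # demographics ------------------------------------------------------------
  set.seed(stage_seed(sc$seed, "demographics"))
  imb <- function(nm) unname(sc$baseline_imbalance[nm] %|na|% 0)
  p_female <- ifelse(is_int, 0.395 + imb("female"), 0.395)
  p_high <- ifelse(is_int, 0.488 + imb("high_education"), 0.488)
  p_rel <- ifelse(is_int, 0.373 + imb("religious"), 0.373)
  p_dutch <- ifelse(is_int, 0.884 + imb("dutch"), 0.884)
  tab$gender <- ifelse(stats::runif(n) < p_female, "female", "male")
  tab$age <- sample(15:19, n, replace = TRUE)
  tab$education <- ifelse(stats::runif(n) < p_high, "high", "low")
  religious <- stats::runif(n) < p_rel
  denom <- sample(c("Catholic", "Protestant", "Muslim", "other"), n,
                  replace = TRUE, prob = c(0.58, 0.17, 0.15, 0.10))
  tab$religion <- ifelse(religious, denom, "none")
  dutch <- stats::runif(n) < p_dutch
  minority <- sample(setdiff(ethnicity_levels(), "Dutch"), n, replace = TRUE,
                     prob = c(0.02, 0.04, 0.05, 0.10, 0.13, 0.18, 0.48))
  tab$ethnicity <- ifelse(dutch, "Dutch", minority)

  # outcomes ----------------------------------------------------------------
  set.seed(stage_seed(sc$seed, "outcomes"))
  w <- sc$weekly_t0_model
  tab$weekly_glasses_t0 <- draw_ziln(n, w$p_zero, w$mu, w$dispersion)
  b <- sc$binge_t0_model
  tab$binge_t0 <- pmin(30, draw_zinb(n, b$p_zero, b$mu, b$dispersion))

  change_latent <- function(sd_tot, icc, drift, effect) {
    u <- stats::rnorm(2L * k, 0, sqrt(icc) * sd_tot)[match(tab$cluster_id, cluster_ids)]
    e <- stats::rnorm(n, 0, sqrt(1 - icc) * sd_tot)
    -drift + effect * is_int + u + e
  }
  ch_w <- change_latent(sc$sd_change_weekly, sc$icc_weekly,
                        sc$secular_drift, sc$arm_effect_weekly)
  ch_b <- change_latent(sc$sd_change_binge, sc$icc_binge,
                        sc$secular_drift_binge, sc$arm_effect_binge)
  tab$weekly_glasses_t1 <- pmax(0, tab$weekly_glasses_t0 - ch_w)
  tab$binge_t1 <- pmin(30, pmax(0, round(tab$binge_t0 - ch_b)))

  # volumes -----------------------------------------------------------------
  set.seed(stage_seed(sc$seed, "volumes"))
  cats <- cost_categories()
  for (cat in cats$category) {
    mdl <- sc$volume_models[[cat]]
    tab[[cat]] <- if (identical(mdl$type, "hours")) {
      draw_ziln(n, mdl$p_zero, mdl$mu, mdl$dispersion)
    } else {
      draw_zinb(n, mdl$p_zero, mdl$mu, mdl$dispersion)
    }
  }

  # questionnaire completeness ----------------------------------------------
  set.seed(stage_seed(sc$seed, "answers"))
  tab$cost_answers_present_t0 <- stats::runif(n) >= sc$missing_cost_t0_rate
  tab$cost_answers_present_t1 <- stats::runif(n) >= sc$missing_cost_t1_rate

  # contamination -----------------------------------------------------------
  contaminated <- character(0)
  if (sc$contamination_rate > 0) {
    set.seed(stage_seed(sc$seed, "contamination"))
    inj <- inject_contamination(tab, rate = sc$contamination_rate,
                                magnitude_factor = sc$contamination_magnitude)
    tab <- inj$table
    contaminated <- inj$flags
  }

  # dropout -----------------------------------------------------------------
  dropouts <- character(0)
  if (sc$dropout_rate > 0) {
    set.seed(stage_seed(sc$seed, "dropout"))
    dp <- apply_dropout(tab, rate = sc$dropout_rate,
                        weights = sc$dropout_covariate_weights)
    tab <- dp$table
    dropouts <- dp$dropout_ids
  }

  exp_vol <- vapply(sc$volume_models[cats$category],
                    function(m) (1 - m$p_zero) * m$mu, numeric(1))
  truth <- list(
    arm_effect_weekly = sc$arm_effect_weekly,
    arm_effect_binge = sc$arm_effect_binge,
    icc_weekly = sc$icc_weekly,
    icc_binge = sc$icc_binge,
    true_mean_volumes = list(intervention = exp_vol, control = exp_vol),
    contaminated_ids = contaminated,
    dropout_ids = dropouts
  )
  structure(list(participants = tab, truth = truth), class = "cea_trial")
}

# NA-tolerant name lookup used for imbalance offsets.
`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Inject systematic unrealistic answers
#'
#' Flags a random subsample of participants and overwrites, for each, at
#' least two randomly chosen volume fields with values of at least
#' `magnitude_factor` times the plausibility limit (the number of spoiled
#' fields is `2 + Poisson(0.9)`, mean 2.9).  This emulates respondents who
#' deliberately and systematically fill in absurd quantities in open-ended
#' questionnaires.
#'
#' @param table Participant data frame.
#' @param rate Fraction flagged, in `[0, 1)`.
#' @param magnitude_factor Multiplier (> 1) on the plausibility limit.
#' @param limits A [plausibility_limits()] object; defaults to the shipped
#'   example limits.
#' @return List with `table` (modified copy) and `flags` (participant ids).
#' @export
inject_contamination <- function(table, rate, magnitude_factor,
                                 limits = default_limits()) {
  check_fraction(rate, "rate")
  if (magnitude_factor <= 1) stop("'magnitude_factor' must be > 1")
  if (rate == 0) {
    return(list(table = table, flags = character(0)))
  }
  cats <- intersect(cost_categories()$category, names(table))
  kind <- cost_categories()
  flagged <- which(stats::runif(nrow(table)) < rate)
  for (i in flagged) {
    n_fields <- min(2 + stats::rpois(1, 0.9), length(cats))
    fields <- sample(cats, n_fields)
    for (f in fields) {
      lim <- limits$limits[[f]]
      val <- lim * magnitude_factor * (1 + stats::runif(1))
      if (kind$kind[kind$category == f] != "hours") val <- ceiling(val)
      table[[f]][i] <- val
    }
  }
  list(table = table, flags = table$participant_id[flagged])
}

#' Apply covariate-dependent dropout at follow-up
#'
#' Clears the follow-up outcome fields and the follow-up cost-answer flag
#' for a logistically selected subset.  The linear predictor is
#' `qlogis(rate) + sum(w_k * (x_k - mean(x_k)))` over centered covariates,
#' so with zero weights the marginal dropout probability is `rate`, and
#' any non-zero weight makes missingness depend on observables
#' (not-at-random relative to the follow-up outcome analysis).
#'
#' @param table Participant data frame.
#' @param rate Marginal dropout probability in `[0, 1)`.
#' @param weights Named numeric vector, see
#'   `dropout_covariate_weights` in [trial_scenario()].
#' @return List with `table` (modified copy) and `dropout_ids`.
#' @export
apply_dropout <- function(table, rate, weights = NULL) {
  check_fraction(rate, "rate")
  if (rate == 0) {
    return(list(table = table, dropout_ids = character(0)))
  }
  lin <- stats::qlogis(rate)
  if (length(weights)) {
    covs <- list(
      age = table$age,
      male = as.numeric(table$gender == "male"),
      female = as.numeric(table$gender == "female"),
      high_education = as.numeric(table$education == "high"),
      religious = as.numeric(table$religion != "none"),
      dutch = as.numeric(table$ethnicity == "Dutch"),
      weekly_glasses_t0 = table$weekly_glasses_t0,
      binge_t0 = table$binge_t0
    )
    for (nm in names(weights)) {
      if (is.null(covs[[nm]])) stop("unknown dropout covariate: ", nm)
      x <- covs[[nm]]
      lin <- lin + weights[[nm]] * (x - mean(x))
    }
  }
  p <- stats::plogis(lin)
  drop <- stats::runif(nrow(table)) < p
  table$weekly_glasses_t1[drop] <- NA_real_
  table$binge_t1[drop] <- NA_real_
  table$cost_answers_present_t1[drop] <- NA
  list(table = table, dropout_ids = table$participant_id[drop])
}

#' Write a synthetic trial to disk
#'
#' Participants as CSV (missing follow-up encoded as empty string) with a
#' ground-truth JSON sidecar.
#'
#' @param trial Result of [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "cea_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "participants.csv")
  json <- file.path(dir, "ground_truth.json")
  utils::write.csv(trial$participants, csv, row.names = FALSE, na = "")
  jsonlite::write_json(trial$truth, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(participants = csv, truth = json))
}

#' Read a participant table written by [write_trial()]
#' @param path CSV file path.
#' @return Participant data frame with typed columns.
#' @export
read_participants <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("weekly_glasses_t0", "weekly_glasses_t1", "binge_t0", "binge_t1")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  for (col in c("cost_answers_present_t0", "cost_answers_present_t1")) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  tab
}
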