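# Screening: plausibility limits, complete-case exclusion rules, and the
# auditable participant-flow report.  All rules use whole-case removal and
# strict inequalities ("more than the limit" excludes; the boundary value
# is retained).  No operation mutates its input.

#' Plausibility limits for volume answers
#'
#' Maximum credible volume per category over the recall window.
#' Day-denominated categories (hospital days) cannot exceed the window
#' length itself.
#'
#' @param limits Named numeric vector, one strictly positive limit per
#'   volume category.
#' @param recall_days Length of the recall window in days (default 120,
#'   a 4-month wave interval).
#' @return Object of class `plausibility_limits`.
#' @export
plausibility_limits <- function(limits, recall_days = 120) {
  limits <- unlist(limits)
  if (any(limits <= 0)) {
    stop("limits must be > 0; offending: ",
         paste(names(limits)[limits <= 0], collapse = ", "))
  }
  cats <- cost_categories()
  day_cats <- intersect(names(limits), cats$category[cats$kind == "days"])
  too_long <- day_cats[limits[day_cats] > recall_days]
  if (length(too_long)) {
    stop("day-denominated limits cannot exceed the recall window (",
         recall_days, " days): ", paste(too_long, collapse = ", "))
  }
  structure(list(limits = limits, recall_days = recall_days),
            class = "plausibility_limits")
}

#' Example plausibility limits shipped with the package
#'
#' User-editable defaults read from `extdata/limits.yaml`; only the
#' 120-hospital-day rule is anchored to the recall window, the rest are
#' deliberately generous round numbers within credibility.
#'
#' @return A [plausibility_limits()] object.
#' @export
default_limits <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "limits.yaml",
                                     package = "ceatrial", mustWork = TRUE))
  plausibility_limits(cfg$limits, recall_days = cfg$recall_days %||% 120)
}

#' Which categories of a record breach their plausibility limit?
#'
#' A category is flagged iff its volume is strictly greater than the
#' limit ("more than" the limit is unrealistic; the limit itself is not).
#'
#' @param record One-row data frame or named list of volumes.
#' @param limits A [plausibility_limits()] object covering every volume
#'   category present.
#' @return Character vector of violated categories (possibly empty).
#' @export
flag_unrealistic <- function(record, limits = default_limits()) {
  cats <- intersect(cost_categories()$category, names(record))
  uncovered <- setdiff(cats, names(limits$limits))
  if (length(uncovered)) {
    stop("limits do not cover: ", paste(uncovered, collapse = ", "))
  }
  vals <- vapply(cats, function(f) as.numeric(record[[f]][1]), numeric(1))
  cats[!is.na(vals) & vals > limits$limits[cats]]
}

# Logical vector: row breaches >= 1 limit.
breaches_any <- function(table, limits) {
  cats <- intersect(cost_categories()$category, names(table))
  uncovered <- setdiff(cats, names(limits$limits))
  if (length(uncovered)) {
    stop("limits do not cover: ", paste(uncovered, collapse = ", "))
  }
  bad <- rep(FALSE, nrow(table))
  for (f in cats) {
    bad <- bad | (!is.na(table[[f]]) & table[[f]] > limits$limits[[f]])
  }
  bad
}

stage_row <- function(label, n_before, n_excluded) {
  data.frame(label = label, n_before = n_before, n_excluded = n_excluded,
             n_after = n_before - n_excluded, stringsAsFactors = FALSE)
}

#' Baseline screening
#'
#' Removes, in this order: (1) participants breaching any plausibility
#' limit (systematic unrealistic answering), then (2) participants who did
#' not answer a single cost question at baseline.  Whole cases are
#' removed; the order matters and is fixed.
#'
#' @param table Participant data frame (nonempty).
#' @param limits A [plausibility_limits()] object.
#' @return List with `table` (screened copy) and `stages` (data frame of
#'   flow stages, chainable into [build_flow_report()]).
#' @export
screen_baseline <- function(table, limits = default_limits()) {
  if (!nrow(table)) stop("empty participant table")
  bad <- breaches_any(table, limits)
  s1 <- stage_row("unrealistic answers (T0)", nrow(table), sum(bad))
  t1 <- table[!bad, , drop = FALSE]
  no_cost <- !t1$cost_answers_present_t0
  s2 <- stage_row("no cost answers at T0", nrow(t1), sum(no_cost))
  t2 <- t1[!no_cost, , drop = FALSE]
  list(table = t2, stages = rbind(s1, s2))
}

#' Follow-up screening
#'
#' Removes, in this order: (1) participants with no follow-up measurement
#' (dropouts, identified by a missing follow-up outcome), then (2)
#' participants breaching any plausibility limit, then (3) participants
#' who did not answer the cost questions at follow-up.
#'
#' @inheritParams screen_baseline
#' @return List with `table` and `stages` as in [screen_baseline()].
#' @export
screen_followup <- function(table, limits = default_limits()) {
  if (!nrow(table)) stop("empty participant table")
  gone <- is.na(table$weekly_glasses_t1)
  s1 <- stage_row("did not participate at T1", nrow(table), sum(gone))
  t1 <- table[!gone, , drop = FALSE]
  bad <- breaches_any(t1, limits)
  s2 <- stage_row("unrealistic answers (T1)", nrow(t1), sum(bad))
  t2 <- t1[!bad, , drop = FALSE]
  no_cost <- is.na(t2$cost_answers_present_t1) | !t2$cost_answers_present_t1
  s3 <- stage_row("no cost answers at T1", nrow(t2), sum(no_cost))
  t3 <- t2[!no_cost, , drop = FALSE]
  list(table = t3, stages = rbind(s1, s2, s3))
}

#' Exclude total-cost outliers
#'
#' Drops participants whose perspective total is strictly greater than the
#' threshold (the threshold value itself is retained).
#'
#' @param cost_table A [cost_breakdown_table()] result (or any data frame
#'   with `participant_id` and the perspective total column).
#' @param threshold Euro threshold (> 0); 5000 is the customary outlier
#'   rule for short-horizon adolescent cost data.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return List with `table` (retained rows) and `excluded_ids`.
#' @export
exclude_cost_outliers <- function(cost_table, threshold = 5000,
                                  perspective = c("societal", "healthcare")) {
  perspective <- match.arg(perspective)
  if (threshold <= 0) stop("'threshold' must be > 0")
  col <- switch(perspective,
                societal = "societal_perspective_total",
                healthcare = "healthcare_perspective_total")
  out <- cost_table[[col]] > threshold
  list(table = cost_table[!out, , drop = FALSE],
       excluded_ids = cost_table$participant_id[out])
}

#' Build a participant-flow report
#'
#' Chains screening stages into a report with exclusion percentages.
#' Stages must chain exactly (`n_after` of one stage equals `n_before` of
#' the next).
#'
#' @param stages Data frame with `label`, `n_before`, `n_excluded`,
#'   `n_after` rows, e.g. `rbind()` of [screen_baseline()] and
#'   [screen_followup()] stages.
#' @param digits Decimal places for the percentages.
#' @param rounding Percentage convention passed to [flow_percent()].
#' @return Object of class `flow_report`: the stage table plus
#'   `percentage_excluded` and `percentage_retained` per stage.
#' @export
build_flow_report <- function(stages, digits = 1,
                              rounding = c("half_up", "down")) {
  rounding <- match.arg(rounding)
  if (nrow(stages) > 1 &&
      any(stages$n_after[-nrow(stages)] != stages$n_before[-1])) {
    stop("flow stages do not chain: n_after of each stage must equal ",
         "n_before of the next")
  }
  if (any(stages$n_after != stages$n_before - stages$n_excluded)) {
    stop("flow stages inconsistent: n_after != n_before - n_excluded")
  }
  stages$percentage_excluded <- mapply(
    flow_percent, stages$n_excluded, stages$n_before,
    MoreArgs = list(digits = digits, rounding = rounding))
  stages$percentage_retained <- mapply(
    flow_percent, stages$n_after, stages$n_before,
    MoreArgs = list(digits = digits, rounding = rounding))
  structure(stages, class = c("flow_report", "data.frame"))
}

#' @export
print.flow_report <- function(x, ...) {
  cat("Participant flow\n")
  cat(sprintf("  start: n = %d\n", x$n_before[1]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  - %s: excluded %d (%s%%) -> n = %d\n",
                x$label[i], x$n_excluded[i],
                format(x$percentage_excluded[i]), x$n_after[i]))
  }
  invisible(x)
}
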