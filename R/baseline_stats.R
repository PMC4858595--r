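# Descriptive and diagnostic statistics: change scores, baseline group
# comparisons, cost-skewness z-scores, and the ANOVA variance-components
# intraclass correlation estimator.

#' Outcome change scores (positive = reduction)
#'
#' Follow-up value subtracted from baseline, for both outcomes: positive
#' scores mean a reduction in drinking, negative scores an increase.
#' Defined only for follow-up completers.
#'
#' @param table Participant data frame restricted to follow-up completers.
#' @return Data frame with `participant_id`, `weekly_reduction`
#'   (glasses/week) and `binge_reduction` (occasions/30 days).
#' @export
compute_change_scores <- function(table) {
  miss <- is.na(table$weekly_glasses_t1) | is.na(table$binge_t1)
  if (any(miss)) {
    stop("missing follow-up measurement for participant(s): ",
         paste(utils::head(table$participant_id[miss], 5), collapse = ", "),
         if (sum(miss) > 5) sprintf(" (and %d more)", sum(miss) - 5) else "")
  }
  data.frame(
    participant_id = table$participant_id,
    weekly_reduction = table$weekly_glasses_t0 - table$weekly_glasses_t1,
    binge_reduction = table$binge_t0 - table$binge_t1,
    stringsAsFactors = FALSE
  )
}

#' Pearson chi-square test of independence (uncorrected)
#'
#' Plain `sum((O - E)^2 / E)` with expected counts from the table margins
#' and no continuity correction, as printed in baseline-comparison tables.
#'
#' @param counts Integer matrix of observed counts, at least 2 x 2.
#' @return The X-squared statistic (numeric scalar).
#' @examples
#' chi_square_independence(rbind(c(717, 821), c(578, 377)))
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("'counts' must be at least 2 x 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin")
  }
  unname(stats::chisq.test(counts, correct = FALSE)$statistic)
}

#' Pooled-variance two-sample t statistic (magnitude)
#'
#' Student's t with pooled variance, reported as a magnitude (comparison
#' tables print unsigned t values).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Absolute value of the pooled t statistic.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  abs((mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2)))
}

#' Skewness z-score
#'
#' Adjusted sample skewness G1 divided by its standard error
#' `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))`.  Values above 1.96 indicate a
#' significantly right-skewed distribution, the expected shape for cost
#' data.
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @return The z-score (numeric scalar).
#' @export
skewness_zscore <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("constant input: skewness undefined")
  g1 <- mean((values - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  G1 / se
}

#' Intraclass correlation via one-way ANOVA variance components
#'
#' Method-of-moments estimator: between- and within-cluster mean squares
#' give `s2_between = max(0, (MSB - MSW) / n0)` (with `n0` the
#' imbalance-adjusted average cluster size) and `s2_within = MSW`; the ICC
#' is `rho = s2_between / (s2_between + s2_within)`.  Negative
#' between-cluster estimates are truncated at zero, keeping `rho` in
#' `[0, 1]`.
#'
#' @param values Numeric outcome vector.
#' @param cluster Cluster (school) membership, same length as `values`.
#' @return List of class `icc_result`: `rho`, `s2_between`, `s2_within`,
#'   `n_clusters`.
#' @export
icc_anova <- function(values, cluster) {
  keep <- !is.na(values)
  values <- values[keep]
  cluster <- as.character(cluster)[keep]
  k <- length(unique(cluster))
  if (k < 2) stop("need >= 2 clusters")
  N <- length(values)
  ni <- tapply(values, cluster, length)
  mi <- tapply(values, cluster, mean)
  grand <- mean(values)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((values - mi[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (msb - msw) / n0)
  s2w <- msw
  rho <- if (s2b + s2w > 0) s2b / (s2b + s2w) else 0
  structure(list(rho = rho, s2_between = s2b, s2_within = s2w,
                 n_clusters = k),
            class = "icc_result")
}

#' Baseline comparison table
#'
#' Arm-by-arm descriptives with chi-square statistics for discrete
#' variables and pooled t statistics for continuous ones, in the layout of
#' a trial baseline table.
#'
#' @param table Participant data frame with both arms present.
#' @return Data frame: `variable`, `type`, `statistic`, `p_value`, arm Ns.
#' @export
baseline_comparison <- function(table) {
  int <- table[table$arm == "intervention", , drop = FALSE]
  ctl <- table[table$arm == "control", , drop = FALSE]
  if (!nrow(int) || !nrow(ctl)) stop("both arms must be nonempty")
  rows <- list()
  add_chi <- function(variable, x_int, x_ctl) {
    counts <- rbind(table(factor(x_int)), table(factor(x_ctl,
                    levels = levels(factor(x_int)))))
    stat <- chi_square_independence(t(counts))
    df <- (ncol(counts) - 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, type = "chi_square", statistic = stat,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE),
      n_intervention = length(x_int), n_control = length(x_ctl),
      stringsAsFactors = FALSE)
  }
  add_t <- function(variable, x_int, x_ctl) {
    stat <- two_sample_t(x_int, x_ctl)
    df <- length(x_int) + length(x_ctl) - 2
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, type = "t", statistic = stat,
      p_value = 2 * stats::pt(-stat, df),
      n_intervention = length(x_int), n_control = length(x_ctl),
      stringsAsFactors = FALSE)
  }
  add_t("age", int$age, ctl$age)
  add_chi("gender", int$gender, ctl$gender)
  add_chi("education", int$education, ctl$education)
  add_chi("religion (religious vs not)",
          int$religion != "none", ctl$religion != "none")
  add_chi("ethnicity (Dutch vs not)",
          int$ethnicity == "Dutch", ctl$ethnicity == "Dutch")
  add_chi("never drinkers",
          int$weekly_glasses_t0 == 0 & int$binge_t0 == 0,
          ctl$weekly_glasses_t0 == 0 & ctl$binge_t0 == 0)
  add_chi("binge drinkers", int$binge_t0 > 0, ctl$binge_t0 > 0)
  add_t("binge occasions", int$binge_t0, ctl$binge_t0)
  add_t("weekly alcohol use", int$weekly_glasses_t0, ctl$weekly_glasses_t0)
  do.call(rbind, rows)
}
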