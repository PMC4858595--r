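# The inferential core: incremental costs/effects, point ICER,
# within-arm nonparametric bootstrap, cost-effectiveness plane quadrants,
# median ICER with dominance labels, percentile confidence intervals and
# cost-effectiveness acceptability curves (net-monetary-benefit rule).

#' Arm-level summary
#'
#' @param arm `"intervention"` or `"control"`.
#' @param n Number of analyzed participants (>= 1).
#' @param mean_cost Mean cost per participant in Euros for the chosen
#'   perspective.
#' @param mean_effect Mean effect (change score; positive = reduction).
#' @return Object of class `arm_summary`.
#' @export
arm_summary <- function(arm, n, mean_cost, mean_effect) {
  if (n < 1) stop("'n' must be >= 1")
  structure(list(arm = arm, n = n, mean_cost = mean_cost,
                 mean_effect = mean_effect),
            class = "arm_summary")
}

#' Incremental costs, effects and point ICER
#'
#' Computes `delta_cost = C_i - C_c`, `delta_effect = E_i - E_c` and the
#' point ICER `delta_cost / delta_effect`.  When the intervention is both
#' more effective and less costly the ratio is negative and labelled
#' `"dominant"`; less effective and more costly is `"inferior"`.  A zero
#' incremental effect yields an undefined ICER, signalled by label
#' `"undefined"` and an `NA` ratio rather than an error.
#'
#' @param intervention,control [arm_summary()] objects (or lists with
#'   `mean_cost` and `mean_effect`) on the same perspective and outcome.
#' @return Object of class `incremental_result`: `delta_cost`,
#'   `delta_effect`, `point_icer` (numeric or `NA`), `label` (one of
#'   `"ratio"`, `"dominant"`, `"inferior"`, `"undefined"`).
#' @examples
#' point_increments(arm_summary("intervention", 387, 139.08, -0.78),
#'                  arm_summary("control", 303, 125.32, -1.51))
#' @export
point_increments <- function(intervention, control) {
  dc <- intervention$mean_cost - control$mean_cost
  de <- intervention$mean_effect - control$mean_effect
  if (de == 0) {
    label <- "undefined"
    icer <- NA_real_
  } else {
    icer <- dc / de
    label <- if (de > 0 && dc < 0) "dominant"
             else if (de < 0 && dc > 0) "inferior"
             else "ratio"
  }
  structure(list(delta_cost = dc, delta_effect = de, point_icer = icer,
                 label = label),
            class = "incremental_result")
}

#' Cost-effectiveness plane quadrant
#'
#' `NE`: more effective and more costly; `SE`: more effective, not more
#' costly (dominant); `SW`: not more effective, not more costly; `NW`:
#' not more effective, more costly (inferior).  Boundary convention: zero
#' incremental effect counts as "not more effective" and zero incremental
#' cost as "not more costly", so the origin falls in SW.  The boundaries
#' have measure zero for continuous data; fixing them keeps quadrant
#' proportions reproducible.
#'
#' @param delta_cost,delta_effect Numeric vectors (recycled).
#' @return Character vector with values in `NE`, `SE`, `SW`, `NW`.
#' @export
classify_quadrant <- function(delta_cost, delta_effect) {
  ifelse(delta_effect > 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost > 0, "NW", "SW"))
}

#' Nonparametric bootstrap of incremental costs and effects
#'
#' Resamples participants with replacement within each arm (arm sizes
#' preserved), recomputes arm means of cost and effect jointly, and
#' records one `(delta_cost, delta_effect)` pair per replicate.  The
#' resampling unit is the participant; an optional cluster bootstrap
#' (resampling schools with replacement within arm) is available for
#' designs where the cluster structure matters.
#'
#' @param data Data frame with columns `arm` (values `"intervention"` and
#'   `"control"`), `cost` and `effect`, and `cluster` if
#'   `cluster_bootstrap = TRUE`.
#' @param n_reps Number of replicates (>= 1); 5000 is customary.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param cluster_bootstrap Resample whole clusters instead of
#'   participants (off by default).
#' @return Object of class `cea_bootstrap`: `replicates` (data frame of
#'   `delta_cost`, `delta_effect`, `quadrant`), `n_reps`, `seed`, `point`
#'   ([point_increments()] of the raw arm means), `quadrant_proportions`,
#'   `ci_cost`, `ci_effect` (95% percentile intervals), `arm_n`.
#' @export
bootstrap_cea <- function(data, n_reps = 5000, seed = 1,
                          cluster_bootstrap = FALSE) {
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  for (a in c("intervention", "control")) {
    if (!sum(data$arm == a)) stop("empty arm: ", a)
  }
  set.seed(seed)
  arm_means <- function(a) {
    sub <- data[data$arm == a, , drop = FALSE]
    n <- nrow(sub)
    if (cluster_bootstrap) {
      cl <- split(seq_len(n), as.character(sub$cluster))
      k <- length(cl)
      mc <- numeric(n_reps); me <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        idx <- unlist(cl[sample.int(k, k, replace = TRUE)], use.names = FALSE)
        mc[r] <- mean(sub$cost[idx])
        me[r] <- mean(sub$effect[idx])
      }
    } else {
      idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n_reps)
      mc <- rowMeans(matrix(sub$cost[idx], nrow = n_reps))
      me <- rowMeans(matrix(sub$effect[idx], nrow = n_reps))
    }
    list(cost = mc, effect = me, n = n,
         raw_cost = mean(sub$cost), raw_effect = mean(sub$effect))
  }
  int <- arm_means("intervention")
  ctl <- arm_means("control")
  dc <- int$cost - ctl$cost
  de <- int$effect - ctl$effect
  quad <- classify_quadrant(dc, de)
  point <- point_increments(
    list(mean_cost = int$raw_cost, mean_effect = int$raw_effect),
    list(mean_cost = ctl$raw_cost, mean_effect = ctl$raw_effect))
  qp <- prop.table(table(factor(quad, levels = c("NE", "NW", "SW", "SE"))))
  structure(
    list(replicates = data.frame(delta_cost = dc, delta_effect = de,
                                 quadrant = quad, stringsAsFactors = FALSE),
         n_reps = n_reps, seed = seed, point = point,
         quadrant_proportions = qp,
         ci_cost = if (n_reps >= 2) percentile_ci(dc) else c(NA, NA),
         ci_effect = if (n_reps >= 2) percentile_ci(de) else c(NA, NA),
         arm_n = c(intervention = int$n, control = ctl$n)),
    class = "cea_bootstrap"
  )
}

#' Median ICER of a bootstrap distribution
#'
#' The 50th percentile of the per-replicate ratios
#' `delta_cost / delta_effect`.  Replicates with a zero incremental effect
#' are dropped from the ratio distribution and counted.  When the point
#' estimate lies in the SE or NW quadrant the result carries the
#' corresponding dominance label (`"dominant"` / `"inferior"`).  Note the
#' raw ratio mixes quadrants with different economic meaning; the
#' CEAC/net-monetary-benefit summaries are the statistically sound
#' companion.
#'
#' @param dist A [bootstrap_cea()] result.
#' @return List of class `median_icer`: `value` (Euro per unit effect, or
#'   `NA` if every replicate had zero incremental effect), `label`
#'   (`"ratio"`, `"dominant"`, `"inferior"` or `"undefined"`),
#'   `n_undefined` (replicates dropped).
#' @export
median_icer <- function(dist) {
  dc <- dist$replicates$delta_cost
  de <- dist$replicates$delta_effect
  ok <- de != 0
  n_undef <- sum(!ok)
  if (!any(ok)) {
    return(structure(list(value = NA_real_, label = "undefined",
                          n_undefined = n_undef),
                     class = "median_icer"))
  }
  val <- unname(stats::quantile(dc[ok] / de[ok], 0.5))
  p <- dist$point
  label <- if (p$label %in% c("dominant", "inferior")) p$label else "ratio"
  structure(list(value = val, label = label, n_undefined = n_undef),
            class = "median_icer")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda`, the probability that
#' the intervention is cost-effective is the fraction of bootstrap
#' replicates with positive net monetary benefit,
#' `lambda * delta_effect - delta_cost > 0`.  At `lambda = 0` this equals
#' the fraction of replicates in which the intervention is cost-saving
#' (SE + SW mass); as `lambda` grows it approaches the fraction with a
#' positive incremental effect.
#'
#' @param dist A [bootstrap_cea()] result.
#' @param wtp_grid Strictly increasing nonnegative Euro grid; the default
#'   0-1000 in steps of 10 covers typical behavioural-outcome thresholds.
#' @return Object of class `ceac_curve`: data frame with `wtp` and
#'   `probability`.
#' @export
ceac <- function(dist, wtp_grid = seq(0, 1000, by = 10)) {
  if (any(wtp_grid < 0) || any(diff(wtp_grid) <= 0)) {
    stop("'wtp_grid' must be nonnegative and strictly increasing")
  }
  dc <- dist$replicates$delta_cost
  de <- dist$replicates$delta_effect
  prob <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Percentile confidence interval
#'
#' Plain percentile interval at `(1 - level)/2` and `1 - (1 - level)/2`
#' using the standard sample-quantile definition (type 7: linear
#' interpolation of order statistics).
#'
#' @param values Numeric vector, n >= 2.
#' @param level Confidence level strictly between 0 and 1.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (length(values) < 2) stop("need n >= 2")
  q <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' @export
print.cea_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap CEA: %d replicates (seed %s)\n", x$n_reps,
              format(x$seed)))
  cat(sprintf("  point: dC = %.2f, dE = %.3f, ICER = %s (%s)\n",
              x$point$delta_cost, x$point$delta_effect,
              if (is.na(x$point$point_icer)) "NA"
              else sprintf("%.2f", x$point$point_icer),
              x$point$label))
  qp <- round(100 * x$quadrant_proportions)
  cat(sprintf("  quadrants: NE %d%%, NW %d%%, SW %d%%, SE %d%%\n",
              qp[["NE"]], qp[["NW"]], qp[["SW"]], qp[["SE"]]))
  invisible(x)
}
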