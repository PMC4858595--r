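# Incremental results, bootstrap engine, quadrants, median ICER, CEAC,
# percentile intervals.

test_that("point increments reproduce arm-mean arithmetic", {
  inc <- point_increments(arm_summary("intervention", 387, 139.08, -0.78),
                          arm_summary("control", 303, 125.32, -1.51))
  expect_equal(inc$delta_cost, 13.76)
  expect_equal(inc$delta_effect, 0.73)
  expect_equal(round(inc$point_icer, 2), 18.85)
  expect_identical(inc$label, "ratio")
})

test_that("dominance labelling and the undefined-ICER signal", {
  dom <- point_increments(list(mean_cost = 10, mean_effect = 2),
                          list(mean_cost = 20, mean_effect = 1))
  expect_identical(dom$label, "dominant")
  inf <- point_increments(list(mean_cost = 20, mean_effect = 1),
                          list(mean_cost = 10, mean_effect = 2))
  expect_identical(inf$label, "inferior")
  undef <- point_increments(list(mean_cost = 20, mean_effect = 1),
                            list(mean_cost = 10, mean_effect = 1))
  expect_identical(undef$label, "undefined")
  expect_true(is.na(undef$point_icer))
  same <- point_increments(list(mean_cost = 5, mean_effect = 1),
                           list(mean_cost = 5, mean_effect = 1))
  expect_identical(same$label, "undefined")
  expect_identical(same$delta_cost, 0)
})

test_that("quadrant classification follows the boundary convention", {
  expect_identical(classify_quadrant(1, 1), "NE")
  expect_identical(classify_quadrant(-1, 1), "SE")
  expect_identical(classify_quadrant(-1, -1), "SW")
  expect_identical(classify_quadrant(1, -1), "NW")
  # zero dE = "not more effective"; zero dC = "not more costly"
  expect_identical(classify_quadrant(0, 0), "SW")
  expect_identical(classify_quadrant(0, 1), "SE")
  expect_identical(classify_quadrant(1, 0), "NW")
  expect_identical(classify_quadrant(c(1, -1), c(1, 1)), c("NE", "SE"))
})

test_that("constant within-arm data collapse the bootstrap to the point", {
  d <- toy_cea_data(rep(100, 4), rep(2, 4), rep(80, 4), rep(1, 4))
  b <- bootstrap_cea(d, n_reps = 200, seed = 1)
  expect_true(all(b$replicates$delta_cost == 20))
  expect_true(all(b$replicates$delta_effect == 1))
  expect_identical(unname(b$quadrant_proportions[["NE"]]), 1)
  expect_identical(sum(b$quadrant_proportions), 1)
  expect_identical(unname(b$ci_cost), c(20, 20))
})

test_that("the same seed reproduces the bootstrap exactly", {
  set.seed(33)
  d <- toy_cea_data(rnorm(20, 100, 30), rnorm(20, 1), rnorm(15, 90, 25),
                    rnorm(15, 0.5))
  b1 <- bootstrap_cea(d, n_reps = 300, seed = 42)
  b2 <- bootstrap_cea(d, n_reps = 300, seed = 42)
  expect_identical(b1, b2)
  b3 <- bootstrap_cea(d, n_reps = 300, seed = 43)
  expect_false(identical(b1$replicates, b3$replicates))
  expect_error(bootstrap_cea(d[d$arm == "control", ]), "empty arm")
})

test_that("replicate distribution matches exhaustive enumeration at 2/arm", {
  d <- toy_cea_data(c(100, 20), c(2, -1), c(50, 10), c(1, 0.2))
  exact <- enumerate_bootstrap(d)
  exact_q <- prop.table(table(factor(
    classify_quadrant(exact$delta_cost, exact$delta_effect),
    levels = c("NE", "NW", "SW", "SE"))))
  n_reps <- 5000
  b <- bootstrap_cea(d, n_reps = n_reps, seed = 9)
  for (q in names(exact_q)) {
    p <- exact_q[[q]]
    se3 <- 3 * sqrt(p * (1 - p) / n_reps)
    expect_lt(abs(b$quadrant_proportions[[q]] - p), se3 + 1e-12,
              label = paste("quadrant", q))
  }
  # replicate support is a subset of the enumerated support
  expect_true(all(round(b$replicates$delta_cost, 9) %in%
                    round(exact$delta_cost, 9)))
})

test_that("bootstrap mean converges to the point estimate (LLN)", {
  set.seed(8)
  d <- toy_cea_data(rlnorm(40, 4, 1), rnorm(40, 1, 2),
                    rlnorm(40, 4, 1), rnorm(40, 0.3, 2))
  b <- bootstrap_cea(d, n_reps = 50000, seed = 4)
  se <- sd(b$replicates$delta_cost) / sqrt(b$n_reps)
  expect_lt(abs(mean(b$replicates$delta_cost) - b$point$delta_cost), 3 * se)
  se_e <- sd(b$replicates$delta_effect) / sqrt(b$n_reps)
  expect_lt(abs(mean(b$replicates$delta_effect) - b$point$delta_effect),
            3 * se_e)
})

test_that("median ICER: odd-count medians, labels, undefined handling", {
  fake <- function(dc, de, point_dc = 1, point_de = 1) {
    structure(list(replicates = data.frame(delta_cost = dc, delta_effect = de,
                   quadrant = classify_quadrant(dc, de)),
                   n_reps = length(dc),
                   point = point_increments(
                     list(mean_cost = point_dc, mean_effect = point_de),
                     list(mean_cost = 0, mean_effect = 0))),
              class = "cea_bootstrap")
  }
  expect_identical(median_icer(fake(10, 2))$value, 5)
  m <- median_icer(fake(c(10, 20, 30), c(1, 1, 1)))
  expect_identical(m$value, 20)
  expect_identical(m$label, "ratio")
  # independently sorted-ratio oracle on a mixed-quadrant set
  dc <- c(10, -5, 8, -2, 7); de <- c(1, 2, -1, -3, 2)
  oracle <- unname(quantile(sort(dc / de), 0.5))
  expect_equal(median_icer(fake(dc, de))$value, oracle)
  # zero-dE replicates are dropped and counted
  mz <- median_icer(fake(c(10, 99, 30), c(1, 0, 1)))
  expect_identical(mz$value, 20)
  expect_identical(mz$n_undefined, 1L)
  expect_identical(median_icer(fake(c(1, 2), c(0, 0)))$label, "undefined")
  # dominance label carried from the point estimate
  expect_identical(median_icer(fake(-10, 2, point_dc = -1, point_de = 1))$label,
                   "dominant")
  expect_identical(median_icer(fake(10, -2, point_dc = 1, point_de = -1))$label,
                   "inferior")
})

test_that("CEAC follows the net-monetary-benefit rule", {
  fake <- function(dc, de) {
    structure(list(replicates = data.frame(delta_cost = dc,
                                           delta_effect = de)),
              class = "cea_bootstrap")
  }
  # all replicates dominant -> probability 1 everywhere
  all_dom <- ceac(fake(rep(-1, 10), rep(1, 10)), seq(0, 100, 10))
  expect_true(all(all_dom$probability == 1))
  # at lambda = 0 the probability is the cost-saving (dC < 0) mass
  dc <- c(-5, -1, 2, 3); de <- c(1, -1, 2, -2)
  curve <- ceac(fake(dc, de), c(0, 50))
  expect_identical(curve$probability[1], mean(dc < 0))
  # hand count at lambda = 50: NMB = 50*de - dc
  expect_identical(curve$probability[2], mean(50 * de - dc > 0))
  # ten hand-listed replicates at lambda = 50
  dc10 <- c(10, 200, -30, 45, 90, 120, -10, 60, 5, 300)
  de10 <- c(1, 2, -0.5, 1.5, 0.5, 3, 0.2, -1, 0.1, 2)
  expect_identical(ceac(fake(dc10, de10), c(50))$probability,
                   mean(50 * de10 - dc10 > 0))
  expect_error(ceac(fake(1, 1), c(10, 5)), "increasing")
  expect_error(ceac(fake(1, 1), c(-10, 5)), "nonnegative")
})

test_that("CEAC is nondecreasing when every replicate has dE >= 0, with the
           large-lambda limit equal to the positive-effect mass", {
  set.seed(12)
  dc <- rnorm(400, 20, 40)
  de <- abs(rnorm(400, 0.5, 0.5)) * rbinom(400, 1, 0.9)
  fake <- structure(list(replicates = data.frame(delta_cost = dc,
                                                 delta_effect = de)),
                    class = "cea_bootstrap")
  curve <- ceac(fake, seq(0, 2000, 20))
  expect_true(all(diff(curve$probability) >= 0))
  # limit: every positive-effect replicate, plus cost-saving zero-effect ones
  lim <- ceac(fake, c(0, 1e9))$probability[2]
  expect_equal(lim, mean(de > 0 | (de == 0 & dc < 0)))
  # with strictly positive costs the limit is exactly the dE > 0 mass
  fake_pos <- structure(list(replicates = data.frame(
    delta_cost = abs(dc) + 0.01, delta_effect = de)),
    class = "cea_bootstrap")
  expect_equal(ceac(fake_pos, c(0, 1e9))$probability[2], mean(de > 0))
})

test_that("percentile intervals match the quantile oracle and validate input", {
  v <- 1:100
  ci <- percentile_ci(v, 0.95)
  expect_equal(unname(ci), unname(quantile(v, c(0.025, 0.975), type = 7)))
  expect_identical(unname(percentile_ci(rep(7, 5))), c(7, 7))
  expect_error(percentile_ci(v, 0), "level")
  expect_error(percentile_ci(v, 1), "level")
  expect_error(percentile_ci(3), "n >= 2")
})

test_that("cluster bootstrap runs and respects the seed", {
  d <- toy_cea_data(rnorm(30, 100, 10), rnorm(30, 1), rnorm(30, 90, 10),
                    rnorm(30, 0.5))
  d$cluster <- rep(sprintf("S%d", 1:6), 10)
  b1 <- bootstrap_cea(d, n_reps = 50, seed = 2, cluster_bootstrap = TRUE)
  b2 <- bootstrap_cea(d, n_reps = 50, seed = 2, cluster_bootstrap = TRUE)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(nrow(b1$replicates), 50L)
})
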