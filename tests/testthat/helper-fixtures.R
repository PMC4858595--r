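# Shared fixtures built in code.

# A small, fast scenario: 4 schools/arm x 15, no contamination/dropout
# unless asked for.
small_scenario <- function(...) {
  args <- list(n_clusters_per_arm = 4, cluster_size_mean = 15,
               contamination_rate = 0, dropout_rate = 0, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trial_scenario, args)
}

# Scenario kept away from the zero floor of the outcomes so that the
# additive cluster/effect structure is undistorted: high positive
# baseline, no zero inflation, modest change noise.
unbounded_scenario <- function(...) {
  args <- list(
    weekly_t0_model = list(p_zero = 0, mu = 60, dispersion = 0.05),
    binge_t0_model = list(p_zero = 0, mu = 15, dispersion = 20),
    sd_change_weekly = 3, sd_change_binge = 1,
    secular_drift = 1.51, secular_drift_binge = 0.33,
    contamination_rate = 0, dropout_rate = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trial_scenario, args)
}

# Minimal participant table with explicit volumes (all other categories 0).
toy_participants <- function(n = 4, arm = rep(c("intervention", "control"),
                                              length.out = n)) {
  tab <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    cluster_id = rep(c("S001", "S002"), length.out = n),
    arm = arm,
    gender = rep(c("male", "female"), length.out = n),
    age = rep(15:19, length.out = n),
    education = rep(c("low", "high"), length.out = n),
    religion = rep(c("none", "Catholic"), length.out = n),
    ethnicity = rep(c("Dutch", "Turkish"), length.out = n),
    weekly_glasses_t0 = 5, weekly_glasses_t1 = 3,
    binge_t0 = 2, binge_t1 = 1,
    cost_answers_present_t0 = TRUE,
    cost_answers_present_t1 = TRUE,
    stringsAsFactors = FALSE
  )
  for (cat in cost_categories()$category) tab[[cat]] <- 0
  tab
}

# Flat unit-cost table: every category 1 Euro in the reference year,
# so costs equal volumes and hand arithmetic stays easy.
flat_unit_costs <- function(price = 1) {
  unit_cost_table(
    data.frame(category = cost_categories()$category,
               unit_price = price, price_year = 2014,
               stringsAsFactors = FALSE),
    index_factors = c("2014" = 1), reference_year = 2014)
}

# Participant-level cost/effect frame for the bootstrap engine.
toy_cea_data <- function(int_cost, int_eff, ctl_cost, ctl_eff) {
  data.frame(
    arm = c(rep("intervention", length(int_cost)),
            rep("control", length(ctl_cost))),
    cost = c(int_cost, ctl_cost),
    effect = c(int_eff, ctl_eff),
    stringsAsFactors = FALSE
  )
}

# Exhaustive within-arm bootstrap enumeration for tiny groups: returns all
# equally likely (delta_cost, delta_effect) pairs.
enumerate_bootstrap <- function(data) {
  tuples <- function(n) {
    g <- do.call(expand.grid, rep(list(seq_len(n)), n))
    as.matrix(g)
  }
  arm_grid <- function(a) {
    sub <- data[data$arm == a, ]
    idx <- tuples(nrow(sub))
    cbind(cost = rowMeans(matrix(sub$cost[idx], nrow(idx))),
          effect = rowMeans(matrix(sub$effect[idx], nrow(idx))))
  }
  gi <- arm_grid("intervention")
  gc <- arm_grid("control")
  combos <- expand.grid(i = seq_len(nrow(gi)), c = seq_len(nrow(gc)))
  data.frame(delta_cost = gi[combos$i, "cost"] - gc[combos$c, "cost"],
             delta_effect = gi[combos$i, "effect"] - gc[combos$c, "effect"])
}
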