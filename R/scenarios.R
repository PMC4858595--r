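# Scenario orchestration: base case, sensitivity scenarios (cost-outlier
# exclusion, substance-cost exclusion) and dichotomized subgroup analyses,
# all driven by one configuration object.

#' Subgroup dichotomization rule
#'
#' @param variable One of `gender`, `age`, `education`, `religion`,
#'   `ethnicity`.
#' @param rule Named character vector mapping each observed raw value to
#'   one of (at most) two labels; a single-label rule gives the degenerate
#'   whole-sample "subgroup" useful for equivalence checks.  For `age`,
#'   `NULL` selects the built-in rule (15-16 vs >= 17, controlled by
#'   `age_threshold`).
#' @param age_threshold First age counted as "older" (default 17).
#' @return Object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(variable, rule = NULL, age_threshold = 17) {
  variable <- match.arg(variable,
                        c("gender", "age", "education", "religion",
                          "ethnicity"))
  if (!is.null(rule) && length(unique(rule)) > 2) {
    stop("subgroup rule must map onto at most two labels")
  }
  structure(list(variable = variable, rule = rule,
                 age_threshold = age_threshold),
            class = "subgroup_spec")
}

#' Default subgroup rules
#'
#' Gender male/female, age 15-16 vs >= 17, educational level low/high,
#' religion religious vs not (any named denomination counts as
#' religious), ethnicity Dutch vs non-Dutch.
#'
#' @return Named list of [subgroup_spec()] objects.
#' @export
default_subgroups <- function() {
  list(
    gender = subgroup_spec("gender",
                           c(male = "male", female = "female")),
    age = subgroup_spec("age"),
    education = subgroup_spec("education", c(low = "low", high = "high")),
    religion = subgroup_spec("religion",
      c(Catholic = "religious", Protestant = "religious",
        Muslim = "religious", other = "religious",
        none = "not religious")),
    ethnicity = subgroup_spec("ethnicity", stats::setNames(
      c("Dutch", rep("non-Dutch", 7)), ethnicity_levels()))
  )
}

#' Dichotomize a background variable
#'
#' Deterministically maps raw values to the two subgroup labels of a
#' [subgroup_spec()].  Values not covered by the rule raise an error.
#'
#' @param values Vector of raw values (or a numeric age vector).
#' @param spec A [subgroup_spec()].
#' @return Character vector of labels.
#' @examples
#' dichotomize(c(16, 17), subgroup_spec("age"))
#' @export
dichotomize <- function(values, spec) {
  if (spec$variable == "age" && is.null(spec$rule)) {
    th <- spec$age_threshold
    return(ifelse(values >= th, sprintf("≥%d", th),
                  sprintf("%d-%d", min(15, th - 2), th - 1)))
  }
  vals <- as.character(values)
  uncovered <- setdiff(unique(vals), names(spec$rule))
  if (length(uncovered)) {
    stop("subgroup rule for '", spec$variable, "' does not cover: ",
         paste(uncovered, collapse = ", "))
  }
  unname(spec$rule[vals])
}

#' Scenario configuration
#'
#' One object driving the base-case, sensitivity and subgroup analyses.
#'
#' @param perspectives Cost perspectives to analyze.
#' @param outcomes Effect measures to analyze (`weekly`, `binge`).
#' @param n_reps Bootstrap replications per analysis (>= 1).
#' @param seed Master seed; each analysis derives a stable sub-seed from
#'   it and its own label, so adding an analysis never changes another.
#' @param outlier_threshold Euro threshold for the cost-outlier
#'   sensitivity scenario (> 0).
#' @param include_substance_costs Include substance-use costs in the
#'   societal perspective of the base case.
#' @param subgroups Named list of [subgroup_spec()]s.
#' @param wtp_max,wtp_step Willingness-to-pay grid for CEACs.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(perspectives = c("healthcare", "societal"),
                            outcomes = c("weekly", "binge"),
                            n_reps = 5000,
                            seed = 1,
                            outlier_threshold = 5000,
                            include_substance_costs = TRUE,
                            subgroups = default_subgroups(),
                            wtp_max = 1000,
                            wtp_step = 10) {
  perspectives <- match.arg(perspectives, c("healthcare", "societal"),
                            several.ok = TRUE)
  outcomes <- match.arg(outcomes, c("weekly", "binge"), several.ok = TRUE)
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (outlier_threshold <= 0) stop("'outlier_threshold' must be > 0")
  structure(
    list(perspectives = perspectives, outcomes = outcomes,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         outlier_threshold = outlier_threshold,
         include_substance_costs = isTRUE(include_substance_costs),
         subgroups = subgroups,
         wtp_grid = seq(0, wtp_max, by = wtp_step)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#' @param path YAML file with any subset of the [scenario_config()]
#'   fields.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scenario_config, cfg[intersect(names(cfg),
    c("perspectives", "outcomes", "n_reps", "seed", "outlier_threshold",
      "include_substance_costs", "wtp_max", "wtp_step"))])
}

#' Screen, cost and score a participant table into an analysis set
#'
#' Runs the full data-preparation chain: baseline screening (plausibility
#' limits, then missing baseline cost answers), follow-up screening
#' (non-participation, limits, missing follow-up cost answers), costing
#' of the complete cases, and change-score computation.  The result is
#' the complete-case analysis table the CEA engine consumes.
#'
#' @param participants Raw participant data frame (e.g. from
#'   [generate_trial()] or [read_participants()]).
#' @param limits A [plausibility_limits()] object.
#' @param unit_costs A [unit_cost_table()].
#' @param intervention_spec An [intervention_cost_spec()].
#' @return List of class `cea_analysis_set`: `data` (one row per analyzed
#'   participant: ids, arm, demographics, `effect_weekly`, `effect_binge`,
#'   `cost_healthcare`, `cost_societal`, `cost_societal_no_substance`),
#'   `flow` (a [build_flow_report()]), `cost_table` (full breakdowns).
#' @export
prepare_analysis_set <- function(participants,
                                 limits = default_limits(),
                                 unit_costs = default_unit_costs(),
                                 intervention_spec = intervention_cost_spec()) {
  base <- screen_baseline(participants, limits)
  fup <- screen_followup(base$table, limits)
  flow <- build_flow_report(rbind(base$stages, fup$stages), digits = 2)
  tab <- fup$table
  costs <- cost_breakdown_table(tab, unit_costs, intervention_spec)
  scores <- compute_change_scores(tab)
  data <- data.frame(
    participant_id = tab$participant_id,
    cluster_id = tab$cluster_id,
    arm = tab$arm,
    gender = tab$gender, age = tab$age, education = tab$education,
    religion = tab$religion, ethnicity = tab$ethnicity,
    effect_weekly = scores$weekly_reduction,
    effect_binge = scores$binge_reduction,
    cost_healthcare = costs$healthcare_perspective_total,
    cost_societal = costs$societal_perspective_total,
    cost_societal_no_substance =
      costs$societal_perspective_total - costs$substance_total,
    stringsAsFactors = FALSE
  )
  structure(list(data = data, flow = flow, cost_table = costs),
            class = "cea_analysis_set")
}

perspective_column <- function(perspective) {
  switch(perspective,
         healthcare = "cost_healthcare",
         societal = "cost_societal",
         societal_no_substance = "cost_societal_no_substance",
         stop("unknown perspective: ", perspective))
}

outcome_column <- function(outcome) {
  switch(outcome,
         weekly = "effect_weekly",
         binge = "effect_binge",
         stop("unknown outcome: ", outcome))
}

# One full engine pass on an analysis data frame.
run_single_cea <- function(data, perspective, outcome, n_reps, seed,
                           wtp_grid) {
  cols <- data.frame(arm = data$arm,
                     cost = data[[perspective_column(perspective)]],
                     effect = data[[outcome_column(outcome)]],
                     cluster = data$cluster_id,
                     stringsAsFactors = FALSE)
  boot <- bootstrap_cea(cols, n_reps = n_reps, seed = seed)
  arms <- lapply(c("intervention", "control"), function(a) {
    sub <- cols[cols$arm == a, ]
    arm_summary(a, nrow(sub), mean(sub$cost), mean(sub$effect))
  })
  names(arms) <- c("intervention", "control")
  list(perspective = perspective, outcome = outcome,
       arms = arms,
       increments = boot$point,
       bootstrap = boot,
       icer = median_icer(boot),
       ceac = ceac(boot, wtp_grid))
}

#' Base-case cost-effectiveness analyses
#'
#' One full bootstrap CEA per configured perspective x outcome
#' combination.  A change of perspective changes only the cost column;
#' effects are identical across perspectives.
#'
#' @param analysis A [prepare_analysis_set()] result.
#' @param config A [scenario_config()].
#' @return Named list (`"<perspective>_<outcome>"`) of engine results,
#'   class `cea_bundle_section`.
#' @export
run_base_case <- function(analysis, config = scenario_config()) {
  data <- analysis$data
  out <- list()
  for (p in config$perspectives) {
    for (o in config$outcomes) {
      key <- paste(p, o, sep = "_")
      out[[key]] <- run_single_cea(
        data, p, o, config$n_reps,
        seed = stage_seed(config$seed, paste("base", key)),
        wtp_grid = config$wtp_grid)
    }
  }
  structure(out, class = "cea_bundle_section")
}

#' Sensitivity analyses
#'
#' Scenario A re-runs every base-case analysis after excluding
#' participants whose chosen-perspective total cost is strictly above the
#' outlier threshold.  Scenario B re-runs the societal-perspective
#' analyses with substance-use costs removed.
#'
#' @inheritParams run_base_case
#' @return List with sections `outliers_excluded` and (when the societal
#'   perspective is configured) `no_substance_costs`.
#' @export
run_sensitivity <- function(analysis, config = scenario_config()) {
  data <- analysis$data
  out <- list(outliers_excluded = list(), no_substance_costs = list())
  for (p in config$perspectives) {
    col <- perspective_column(p)
    keep <- data[[col]] <= config$outlier_threshold
    sub <- data[keep, , drop = FALSE]
    for (o in config$outcomes) {
      key <- paste(p, o, sep = "_")
      out$outliers_excluded[[key]] <- run_single_cea(
        sub, p, o, config$n_reps,
        seed = stage_seed(config$seed, paste("outlier", key)),
        wtp_grid = config$wtp_grid)
      out$outliers_excluded[[key]]$excluded_ids <-
        data$participant_id[!keep]
    }
  }
  if ("societal" %in% config$perspectives) {
    for (o in config$outcomes) {
      key <- paste("societal_no_substance", o, sep = "_")
      out$no_substance_costs[[key]] <- run_single_cea(
        data, "societal_no_substance", o, config$n_reps,
        seed = stage_seed(config$seed, paste("nosubst", key)),
        wtp_grid = config$wtp_grid)
    }
  }
  out
}

#' Subgroup cost-effectiveness analyses
#'
#' Dichotomizes each configured background variable and reruns the full
#' engine per subgroup level, perspective and outcome.  A subgroup level
#' with an empty arm is skipped with a warning rather than an error
#' (small cells are expected in stratified trial data).  Each subgroup
#' derives its seed from the master seed and its own label, so adding a
#' subgroup never changes the others.
#'
#' @inheritParams run_base_case
#' @return Nested list: variable -> level -> `"<perspective>_<outcome>"`.
#' @export
run_subgroups <- function(analysis, config = scenario_config()) {
  data <- analysis$data
  out <- list()
  for (vn in names(config$subgroups)) {
    spec <- config$subgroups[[vn]]
    labels <- dichotomize(data[[spec$variable]], spec)
    for (lv in sort(unique(labels))) {
      sub <- data[labels == lv, , drop = FALSE]
      if (!all(c("intervention", "control") %in% unique(sub$arm))) {
        warning(sprintf("subgroup %s=%s: empty arm cell, skipped", vn, lv))
        next
      }
      for (p in config$perspectives) {
        for (o in config$outcomes) {
          key <- paste(p, o, sep = "_")
          res <- run_single_cea(
            sub, p, o, config$n_reps,
            seed = stage_seed(config$seed, paste("subgroup", vn, lv, key)),
            wtp_grid = config$wtp_grid)
          res$n <- nrow(sub)
          out[[vn]][[lv]][[key]] <- res
        }
      }
    }
  }
  out
}

#' Run every configured analysis
#'
#' Orchestrates data preparation (when given raw participants), the base
#' case, sensitivity scenarios and subgroup analyses into one bundle
#' ready for [render_reports()].
#'
#' @param participants Raw participant table, or a prepared
#'   `cea_analysis_set`.
#' @param config A [scenario_config()].
#' @param limits,unit_costs,intervention_spec Passed to
#'   [prepare_analysis_set()] when `participants` is a raw table.
#' @return List of class `cea_bundle`: `analysis`, `base`, `sensitivity`,
#'   `subgroups`, `config`.
#' @export
run_scenarios <- function(participants, config = scenario_config(),
                          limits = default_limits(),
                          unit_costs = default_unit_costs(),
                          intervention_spec = intervention_cost_spec()) {
  analysis <- if (inherits(participants, "cea_analysis_set")) participants
              else prepare_analysis_set(participants, limits, unit_costs,
                                        intervention_spec)
  structure(
    list(analysis = analysis,
         base = run_base_case(analysis, config),
         sensitivity = run_sensitivity(analysis, config),
         subgroups = run_subgroups(analysis, config),
         config = config),
    class = "cea_bundle"
  )
}
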