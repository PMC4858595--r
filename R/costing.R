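# Costing: volumes -> Euros, sector classification, price indexing,
# perspective totals.  Currency arithmetic is done on cents (rounded
# half-up at the category level) so that sector and perspective totals are
# exactly the sums of their members.

round_cents <- function(x) round_half_up(x, 2)

#' Assemble a unit-cost table
#'
#' @param entries Data frame with columns `category`, `unit_price` (Euros
#'   per unit in `price_year` prices) and `price_year`.
#' @param index_factors Named numeric vector/list mapping calendar years
#'   to price-index multipliers relative to the reference year; the
#'   reference-year factor must be 1.
#' @param reference_year Year all prices are indexed to.
#' @param sector_map Optional named character vector overriding the
#'   canonical category-to-sector assignment of [cost_categories()].
#' @return Object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(entries, index_factors, reference_year = 2014,
                            sector_map = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("category", "unit_price", "price_year") %in% names(entries)))
  if (any(entries$unit_price < 0)) {
    stop("configuration error: negative unit_price for ",
         paste(entries$category[entries$unit_price < 0], collapse = ", "))
  }
  canon <- cost_categories()
  if (is.null(sector_map)) {
    sector_map <- stats::setNames(canon$sector, canon$category)
  }
  no_sector <- setdiff(entries$category, names(sector_map))
  if (length(no_sector)) {
    stop("configuration error: no sector for ",
         paste(no_sector, collapse = ", "))
  }
  fac <- unlist(index_factors)
  names(fac) <- as.character(names(fac))
  ref <- fac[as.character(reference_year)]
  if (is.na(ref) || abs(ref - 1) > 1e-9) {
    stop("configuration error: index factor for the reference year must be 1")
  }
  entries$sector <- unname(sector_map[entries$category])
  structure(
    list(entries = entries, index_factors = fac,
         reference_year = reference_year, sector_map = sector_map),
    class = "unit_cost_table"
  )
}

#' Read a unit-cost table from YAML
#'
#' Expected layout: `reference_year`, `index_factors: {year: factor}`, and
#' `categories: {name: {unit_price: x, price_year: y}}`.
#'
#' @param path YAML file.
#' @return A [unit_cost_table()].
#' @export
read_unit_costs <- function(path) {
  cfg <- yaml::read_yaml(path)
  ent <- data.frame(
    category = names(cfg$categories),
    unit_price = vapply(cfg$categories, function(x) as.numeric(x$unit_price),
                        numeric(1)),
    price_year = vapply(cfg$categories, function(x) as.integer(x$price_year),
                        integer(1)),
    stringsAsFactors = FALSE
  )
  unit_cost_table(ent, cfg$index_factors,
                  reference_year = cfg$reference_year %||% 2014)
}

#' Example unit-cost configuration
#'
#' Illustrative prices shipped with the package.  These are placeholders
#' in the spirit of national costing manuals, not the manuals' values;
#' analyses of real data must supply their own table.
#'
#' @return A [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.yaml",
                              package = "ceatrial", mustWork = TRUE))
}

#' Index a price to another calendar year
#'
#' Multiplies by the ratio of index factors,
#' `factor(to_year) / factor(from_year)`, and rounds half-up to the cent.
#'
#' @param price Price in Euros (>= 0).
#' @param from_year,to_year Calendar years present in `index_factors`.
#' @param index_factors Named numeric vector of index multipliers.
#' @return Price in `to_year` Euros.
#' @examples
#' index_price(100, 2012, 2014, c("2012" = 1.00, "2014" = 1.05))
#' @export
index_price <- function(price, from_year, to_year, index_factors) {
  if (price < 0) stop("configuration error: price must be >= 0")
  fac <- unlist(index_factors)
  f_from <- fac[as.character(from_year)]
  f_to <- fac[as.character(to_year)]
  if (is.na(f_from) || is.na(f_to)) {
    stop("configuration error: unknown index year ",
         paste(c(from_year, to_year)[is.na(c(f_from, f_to))], collapse = ", "))
  }
  round_cents(price * unname(f_to / f_from))
}

#' Specify the per-participant intervention cost build-up
#'
#' Defaults reproduce a tailored-feedback programme: a software fee of
#' 7 Euro per participant-week over a mean 4-week exposure (28 Euro), plus
#' 1.5 hours of school time at 8.30 Euro/hour and a 12.50 Euro lump value
#' for one hour of free time, the time component rounded to the nearest
#' Euro (25 Euro) -- 53 Euro in total.
#'
#' @param feedback_fee_per_week Euro per participant per week.
#' @param feedback_weeks Mean weeks of feedback exposure.
#' @param school_hours,school_hour_rate Supervised time and its hourly rate.
#' @param free_time_hours,free_time_value Hours of own time and their lump
#'   valuation in Euro.
#' @param rounding `"nearest_euro"` rounds the time component half-up to
#'   whole Euros; `"none"` keeps cents.
#' @return Object of class `intervention_cost_spec`.
#' @export
intervention_cost_spec <- function(feedback_fee_per_week = 7,
                                   feedback_weeks = 4,
                                   school_hours = 1.5,
                                   school_hour_rate = 8.30,
                                   free_time_hours = 1,
                                   free_time_value = 12.50,
                                   rounding = c("nearest_euro", "none")) {
  rounding <- match.arg(rounding)
  vals <- c(feedback_fee_per_week, feedback_weeks, school_hours,
            school_hour_rate, free_time_hours, free_time_value)
  if (any(vals < 0)) stop("intervention cost components must be nonnegative")
  structure(
    list(feedback_fee_per_week = feedback_fee_per_week,
         feedback_weeks = feedback_weeks,
         school_hours = school_hours,
         school_hour_rate = school_hour_rate,
         free_time_hours = free_time_hours,
         free_time_value = free_time_value,
         rounding = rounding),
    class = "intervention_cost_spec"
  )
}

#' Per-participant intervention cost
#'
#' `feedback_fee_per_week * feedback_weeks` plus the (optionally
#' whole-Euro-rounded) participant time component
#' `school_hours * school_hour_rate + free_time_value`.
#'
#' @param spec An [intervention_cost_spec()].
#' @param component `"total"` (default), or just the `"feedback"` or
#'   `"time"` part.
#' @return Cost in Euros.
#' @examples
#' intervention_cost(intervention_cost_spec())            # 53
#' intervention_cost(intervention_cost_spec(), "feedback") # 28
#' @export
intervention_cost <- function(spec = intervention_cost_spec(),
                              component = c("total", "feedback", "time")) {
  component <- match.arg(component)
  feedback <- spec$feedback_fee_per_week * spec$feedback_weeks
  time_part <- spec$school_hours * spec$school_hour_rate + spec$free_time_value
  if (spec$rounding == "nearest_euro") time_part <- round_half_up(time_part, 0)
  switch(component,
         total = feedback + time_part,
         feedback = feedback,
         time = time_part)
}

value_one_breakdown <- function(vol, arm, unit_costs, intervention_spec,
                                arm_rule) {
  ent <- unit_costs$entries
  prices <- stats::setNames(
    mapply(index_price, ent$unit_price, ent$price_year,
           MoreArgs = list(to_year = unit_costs$reference_year,
                           index_factors = unit_costs$index_factors)),
    ent$category
  )
  unknown <- names(vol)[vol > 0 & !(names(vol) %in% ent$category)]
  if (length(unknown)) {
    stop("configuration error: no unit cost for ",
         paste(unknown, collapse = ", "))
  }
  keep <- intersect(names(vol), ent$category)
  per_category <- round_cents(vol[keep] * prices[keep])
  sec <- unit_costs$sector_map[keep]
  per_sector <- vapply(all_sectors(),
                       function(s) sum(per_category[sec == s]), numeric(1))
  hc <- per_sector[["health_care"]]
  icb <- sum(per_sector[icb_sectors()])
  subst <- per_sector[["substance_use"]]
  ic <- switch(arm_rule,
               intervention_only = if (identical(arm, "intervention"))
                 intervention_cost(intervention_spec) else 0,
               both_arms = intervention_cost(intervention_spec),
               none = 0)
  structure(
    list(per_category = per_category,
         per_sector = per_sector,
         health_care_total = hc,
         icb_total = icb,
         substance_total = subst,
         intervention_cost = ic,
         healthcare_perspective_total = hc + ic,
         societal_perspective_total = hc + icb + subst + ic),
    class = "cost_breakdown"
  )
}

#' Value a participant's volumes in Euros
#'
#' Multiplies each recorded volume by its indexed unit price, aggregates
#' per sector, and assembles the two perspective totals.  The health-care
#' perspective counts health-care services plus the intervention cost; the
#' societal perspective adds the ICB sectors and substance-use costs.
#' Under the default `arm_rule` the intervention cost is attributed to
#' intervention-arm participants only (the comparator receives the
#' programme only after the trial, so its cost does not enter the control
#' arm).
#'
#' @param record A one-row participant data frame or a list with `arm` and
#'   the volume fields.
#' @param unit_costs A [unit_cost_table()].
#' @param intervention_spec An [intervention_cost_spec()].
#' @param arm_rule `"intervention_only"`, `"both_arms"` or `"none"`.
#' @return A `cost_breakdown`: per-category and per-sector Euros plus
#'   `health_care_total`, `icb_total`, `substance_total`,
#'   `intervention_cost`, `healthcare_perspective_total`,
#'   `societal_perspective_total`.
#' @export
value_costs <- function(record, unit_costs = default_unit_costs(),
                        intervention_spec = intervention_cost_spec(),
                        arm_rule = c("intervention_only", "both_arms", "none")) {
  arm_rule <- match.arg(arm_rule)
  cats <- intersect(cost_categories()$category, names(record))
  vol <- vapply(cats, function(f) as.numeric(record[[f]][1]), numeric(1))
  value_one_breakdown(vol, as.character(record[["arm"]][1]), unit_costs,
                      intervention_spec, arm_rule)
}

#' Value every participant in a table
#'
#' Vectorized version of [value_costs()]: one output row per participant
#' with per-category costs, sector totals and both perspective totals.
#'
#' @inheritParams value_costs
#' @param table Participant data frame with `participant_id`, `arm` and
#'   volume columns.
#' @return Data frame of class `cost_table`.
#' @export
cost_breakdown_table <- function(table, unit_costs = default_unit_costs(),
                                 intervention_spec = intervention_cost_spec(),
                                 arm_rule = c("intervention_only",
                                              "both_arms", "none")) {
  arm_rule <- match.arg(arm_rule)
  ent <- unit_costs$entries
  prices <- stats::setNames(
    mapply(index_price, ent$unit_price, ent$price_year,
           MoreArgs = list(to_year = unit_costs$reference_year,
                           index_factors = unit_costs$index_factors)),
    ent$category
  )
  vol_cols <- intersect(cost_categories()$category, names(table))
  extra <- setdiff(vol_cols, ent$category)
  if (length(extra) && any(vapply(extra, function(f) any(table[[f]] > 0),
                                  logical(1)))) {
    stop("configuration error: no unit cost for ",
         paste(extra[vapply(extra, function(f) any(table[[f]] > 0),
                            logical(1))], collapse = ", "))
  }
  use <- intersect(vol_cols, ent$category)
  vols <- as.matrix(table[use])
  costs <- round_cents(sweep(vols, 2, prices[use], `*`))
  sec <- unit_costs$sector_map[use]
  out <- data.frame(participant_id = table$participant_id,
                    arm = table$arm, stringsAsFactors = FALSE)
  for (j in seq_along(use)) out[[paste0("cost_", use[j])]] <- costs[, j]
  for (s in all_sectors()) {
    cols <- which(sec == s)
    out[[paste0("sector_", s)]] <- if (length(cols))
      rowSums(costs[, cols, drop = FALSE]) else 0
  }
  out$health_care_total <- out$sector_health_care
  out$icb_total <- rowSums(out[paste0("sector_", icb_sectors())])
  out$substance_total <- out$sector_substance_use
  ic <- intervention_cost(intervention_spec)
  out$intervention_cost <- switch(arm_rule,
    intervention_only = ifelse(table$arm == "intervention", ic, 0),
    both_arms = ic,
    none = 0)
  out$healthcare_perspective_total <-
    out$health_care_total + out$intervention_cost
  out$societal_perspective_total <-
    out$health_care_total + out$icb_total + out$substance_total +
    out$intervention_cost
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Summarize costs per arm with a bootstrapped median
#'
#' For each cost column: raw mean and SD, plus the median (50th
#' percentile) and variance of `n_boot` resampled group means.  Rows are
#' resampled jointly across columns, so category summaries and totals come
#' from the same replicates.
#'
#' @param cost_table Result of [cost_breakdown_table()].
#' @param n_boot Bootstrap replications (>= 1); 1000 is customary for cost
#'   description tables.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param columns Cost columns to summarize (default: all).
#' @return Data frame: `arm`, `item`, `mean`, `sd`, `boot_median`,
#'   `boot_var`.
#' @export
summarize_costs <- function(cost_table, n_boot = 1000, seed = 1,
                            columns = NULL) {
  if (n_boot < 1) stop("'n_boot' must be >= 1")
  cols <- columns %||% setdiff(names(cost_table), c("participant_id", "arm"))
  arms <- unique(as.character(cost_table$arm))
  set.seed(seed)
  res <- list()
  for (a in arms) {
    sub <- cost_table[cost_table$arm == a, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) stop("empty group: ", a)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    for (col in cols) {
      v <- sub[[col]]
      boot_means <- rowMeans(matrix(v[idx], nrow = n_boot))
      res[[length(res) + 1L]] <- data.frame(
        arm = a, item = col,
        mean = mean(v),
        sd = stats::sd(v),
        boot_median = unname(stats::quantile(boot_means, 0.5)),
        boot_var = stats::var(boot_means),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}
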