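# Report rendering: flat CSV tables mirroring the published table shapes
# (per-arm costs and effects, median ICER, quadrant percentages), plane
# and CEAC point files, and a reproducibility manifest.

# Integer percentages by largest remainder, so the four quadrant shares
# always print as a sum of exactly 100.
round_percent_100 <- function(p) {
  pct <- 100 * p / sum(p)
  fl <- floor(pct)
  short <- round(100 - sum(fl))
  rem <- order(pct - fl, decreasing = TRUE)
  fl[rem[seq_len(short)]] <- fl[rem[seq_len(short)]] + 1
  fl
}

# Flatten one engine result into a two-row (per-arm) summary block.
cea_result_rows <- function(res, scenario, subgroup = "") {
  qp <- round_percent_100(as.numeric(res$bootstrap$quadrant_proportions))
  names(qp) <- names(res$bootstrap$quadrant_proportions)
  icer_txt <- if (res$icer$label %in% c("dominant", "inferior"))
    res$icer$label else format(round_half_up(res$icer$value, 0))
  do.call(rbind, lapply(c("control", "intervention"), function(a) {
    s <- res$arms[[a]]
    data.frame(
      scenario = scenario, subgroup = subgroup,
      perspective = res$perspective, outcome = res$outcome,
      condition = a, n = s$n,
      mean_cost = round_half_up(s$mean_cost, 2),
      mean_effect = round_half_up(s$mean_effect, 2),
      icer = if (a == "intervention") icer_txt else "",
      pct_NE = if (a == "intervention") qp[["NE"]] else NA,
      pct_NW = if (a == "intervention") qp[["NW"]] else NA,
      pct_SW = if (a == "intervention") qp[["SW"]] else NA,
      pct_SE = if (a == "intervention") qp[["SE"]] else NA,
      stringsAsFactors = FALSE
    )
  }))
}

collect_results <- function(bundle) {
  out <- list()
  for (key in names(bundle$base)) {
    out[[length(out) + 1L]] <-
      list(res = bundle$base[[key]], scenario = "base", subgroup = "")
  }
  for (sec in names(bundle$sensitivity)) {
    for (key in names(bundle$sensitivity[[sec]])) {
      out[[length(out) + 1L]] <-
        list(res = bundle$sensitivity[[sec]][[key]], scenario = sec,
             subgroup = "")
    }
  }
  for (vn in names(bundle$subgroups)) {
    for (lv in names(bundle$subgroups[[vn]])) {
      for (key in names(bundle$subgroups[[vn]][[lv]])) {
        out[[length(out) + 1L]] <-
          list(res = bundle$subgroups[[vn]][[lv]][[key]],
               scenario = "subgroup", subgroup = paste(vn, lv, sep = "="))
      }
    }
  }
  out
}

#' Summary table of a scenario bundle
#'
#' @param bundle A [run_scenarios()] result.
#' @return Data frame with one control and one intervention row per
#'   analysis: arm means, median ICER (or dominance label) and integer
#'   quadrant percentages.
#' @export
cea_summary_table <- function(bundle) {
  parts <- collect_results(bundle)
  do.call(rbind, lapply(parts, function(p)
    cea_result_rows(p$res, p$scenario, p$subgroup)))
}

# Cheap deterministic checksum for the manifest (config provenance).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Render a scenario bundle to files
#'
#' Writes `cea_summary.csv` (per-analysis arm summaries, median ICERs,
#' quadrant percentages), `plane_points.csv` and `ceac_points.csv` (full
#' precision bootstrap output for plotting), `participant_flow.csv`, and
#' a `manifest.json` recording the configuration hash, seed and package
#' version.  Rendering is a pure function of the bundle: re-rendering the
#' same bundle reproduces identical files.
#'
#' @param bundle A [run_scenarios()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
render_reports <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  w(cea_summary_table(bundle), "cea_summary.csv")

  parts <- collect_results(bundle)
  plane <- do.call(rbind, lapply(parts, function(p) {
    r <- p$res$bootstrap$replicates
    data.frame(scenario = p$scenario, subgroup = p$subgroup,
               perspective = p$res$perspective, outcome = p$res$outcome,
               delta_cost = r$delta_cost, delta_effect = r$delta_effect,
               quadrant = r$quadrant, stringsAsFactors = FALSE)
  }))
  w(plane, "plane_points.csv")
  curves <- do.call(rbind, lapply(parts, function(p) {
    data.frame(scenario = p$scenario, subgroup = p$subgroup,
               perspective = p$res$perspective, outcome = p$res$outcome,
               wtp = p$res$ceac$wtp, probability = p$res$ceac$probability,
               stringsAsFactors = FALSE)
  }))
  w(curves, "ceac_points.csv")
  w(as.data.frame(bundle$analysis$flow), "participant_flow.csv")

  empty_subgroups <- length(bundle$subgroups) == 0
  manifest <- list(
    config_hash = config_hash(bundle$config),
    seed = bundle$config$seed,
    n_reps = bundle$config$n_reps,
    n_analyzed = nrow(bundle$analysis$data),
    subgroup_section = if (empty_subgroups) "omitted (no subgroups)"
                       else "included",
    package = "ceatrial",
    package_version = as.character(utils::packageVersion("ceatrial")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
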