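#' Run the complete analysis
#'
#' Base-case run for both strategies, incremental outcomes, the scenario
#' suite and the one-way sensitivity analysis, in one call.
#'
#' @param params Parameter ledger (default [base_parameters()]).
#' @param ... Residual-policy arguments passed to the pipeline.
#' @return An `lbp_results` list: `strategies` (per-strategy run
#'   objects), `base` (`lbp_incremental`), `scenarios` (suite table and
#'   results), `dsa` (`lbp_dsa_table`), `ce_plane`, and the `params`
#'   used.
#' @examples
#' \donttest{
#' res <- run_full_analysis()
#' res$base
#' }
#' @export
run_full_analysis <- function(params = base_parameters(), ...) {
  strategies <- lapply(stats::setNames(nm = lbp_strategies()), function(s) {
    run_strategy(params, s, ...)
  })
  base <- incremental_outcomes(strategies$DTC$totals, strategies$TAU$totals)
  scen <- scenario_suite(params, ...)
  dsa <- one_way_dsa(params, ...)
  structure(list(
    params = params,
    strategies = strategies,
    base = base,
    scenarios = scen,
    dsa = dsa,
    ce_plane = ce_plane_points(scen$results)
  ), class = "lbp_results")
}

#' @export
print.lbp_results <- function(x, ...) {
  cat("<lbp_results>\n")
  print(x$base)
  cat(sprintf("  %d scenarios, %d DSA parameters\n",
              nrow(x$scenarios$table), nrow(x$dsa)))
  invisible(x)
}

trace_table <- function(trace, annual_rate, cycles_per_year) {
  n_cycles <- nrow(trace$corrected)
  states <- lbp_states()
  df <- discount_factor(seq_len(n_cycles) - 1, annual_rate, cycles_per_year)
  data.frame(
    cycle = rep(seq_len(n_cycles) - 1, times = 7),
    state = rep(states, each = n_cycles),
    raw_members = as.vector(trace$raw[seq_len(n_cycles), ]),
    corrected_members = as.vector(trace$corrected),
    discount_factor = rep(df, times = 7),
    stringsAsFactors = FALSE
  )
}

#' Serialize analysis results to disk
#'
#' Writes a deterministic file set into `out_dir`:
#' `results.json` (versioned schema: strategy totals, base incremental,
#' scenario table, DSA table), one `trace_<strategy>.csv` per strategy
#' (columns `cycle`, `state`, `raw_members`, `corrected_members`,
#' `discount_factor`), `tornado.csv`, `ce_plane.csv` and
#' `scenarios.csv`. Monetary values are rounded half-up to cents at this
#' boundary only; reruns on identical inputs produce byte-identical
#' files.
#'
#' @param results An `lbp_results` object from [run_full_analysis()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "lbp_results"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("write_results(): cannot create %s", out_dir),
                  call. = FALSE)
  }
  p <- results$params
  cpy <- p$settings$cycles_per_year

  totals_json <- lapply(results$strategies, function(r) {
    t <- r$totals
    list(strategy = t$strategy,
         discounted_cost = round_cents(t$discounted_cost),
         discounted_qalys = round(t$discounted_qalys, 6),
         undiscounted_cost = round_cents(t$undiscounted_cost),
         undiscounted_qalys = round(t$undiscounted_qalys, 6),
         healthy_at_horizon = t$healthy_at_horizon,
         per_state_cost = as.list(round_cents(t$per_state_cost)),
         per_state_qalys = as.list(round(t$per_state_qalys, 6)))
  })
  inc_json <- function(r) {
    list(scenario_id = r$scenario_id,
         delta_cost = round_cents(r$delta_cost),
         delta_qalys = round(r$delta_qalys, 6),
         icer = if (is.na(r$icer_value)) NULL else round_cents(r$icer_value),
         dominance_label = r$dominance_label,
         strict = if (is.na(r$strict)) NULL else r$strict)
  }
  doc <- list(
    schema_version = "1.0",
    settings = p$settings[c("discount_rate", "cycles_per_year", "horizon_years",
                            "cohort_size")],
    strategies = totals_json,
    incremental = inc_json(results$base),
    scenarios = lapply(results$scenarios$results, inc_json),
    dsa = as.data.frame(results$dsa)
  )
  files <- character(0)
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, json_path)

  for (s in names(results$strategies)) {
    f <- file.path(out_dir, sprintf("trace_%s.csv", s))
    utils::write.csv(trace_table(results$strategies[[s]]$trace,
                                 p$settings$discount_rate, cpy),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "tornado.csv")
  utils::write.csv(as.data.frame(results$dsa), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "ce_plane.csv")
  utils::write.csv(results$ce_plane$points, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "scenarios.csv")
  utils::write.csv(results$scenarios$table, f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
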