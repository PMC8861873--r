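#' Define a scenario
#'
#' A scenario reruns the full pipeline with a different horizon and/or
#' alternative monthly attrition rates for the app strategy (treatment
#' as usual stays at base values). Attrition overrides are recomposed
#' into tunnel transition rows through [dropout_split()] with the base
#' remission share and trajectory split.
#'
#' @param scenario_id Scenario label.
#' @param horizon_years Model horizon in years.
#' @param dtc_attrition Optional length-2 vector: app-strategy attrition
#'   after month one and month two.
#' @return An `lbp_scenario_spec` list.
#' @export
scenario_spec <- function(scenario_id, horizon_years = 3, dtc_attrition = NULL) {
  if (!is.null(dtc_attrition)) {
    if (length(dtc_attrition) != 2 || any(dtc_attrition < 0) ||
        any(dtc_attrition > 1)) {
      stop("scenario_spec(): dtc_attrition must be two probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  if (horizon_years < 1) {
    stop("scenario_spec(): horizon_years must be at least 1", call. = FALSE)
  }
  structure(list(scenario_id = scenario_id, horizon_years = horizon_years,
                 dtc_attrition = dtc_attrition),
            class = "lbp_scenario_spec")
}

#' The scenario suite of the reference analysis
#'
#' Base case (3-year horizon, trial attrition rates) plus six published
#' scenarios: alternative horizons of 2, 4 and 5 years (A.1-A.3) and
#' alternative app attrition rates (B.1: lowered to the TAU rates
#' 6.5%/4.3%; B.2: 14% after each of the first two months; B.3: 30%).
#'
#' @return Named list of `lbp_scenario_spec` objects.
#' @export
published_scenarios <- function() {
  list(
    base = scenario_spec("base", 3),
    A1 = scenario_spec("A1", 2),
    A2 = scenario_spec("A2", 4),
    A3 = scenario_spec("A3", 5),
    B1 = scenario_spec("B1", 3, c(0.065, 0.043)),
    B2 = scenario_spec("B2", 3, c(0.14, 0.14)),
    B3 = scenario_spec("B3", 3, c(0.30, 0.30))
  )
}

#' Run one scenario
#'
#' @param spec An `lbp_scenario_spec`.
#' @param params Parameter ledger.
#' @inheritParams run_strategy
#' @return An `lbp_incremental` tagged with the scenario id.
#' @examples
#' run_scenario(scenario_spec("A1", 2), base_parameters())
#' @export
run_scenario <- function(spec, params,
                         residual_policy = "renormalize_non_treatment",
                         eot_residual = "trajectory_split") {
  stopifnot(inherits(spec, "lbp_scenario_spec"),
            inherits(params, "lbp_parameters"))
  p <- params
  if (!is.null(spec$dtc_attrition)) {
    p <- set_attrition(p, "DTC", spec$dtc_attrition)
  }
  runs <- lapply(lbp_strategies(), function(s) {
    run_strategy(p, s, horizon_years = spec$horizon_years,
                 residual_policy = residual_policy,
                 eot_residual = eot_residual)
  })
  incremental_outcomes(runs[[1]]$totals, runs[[2]]$totals,
                       scenario_id = spec$scenario_id)
}

#' Run the whole scenario suite
#'
#' @param params Parameter ledger.
#' @param specs List of scenario specs (default [published_scenarios()]).
#' @param ... Passed on to [run_scenario()].
#' @return List with `results` (list of `lbp_incremental`) and `table`
#'   (a data.frame with one row per scenario: incremental cost and
#'   effect, ICER where defined, dominance label).
#' @export
scenario_suite <- function(params, specs = published_scenarios(), ...) {
  results <- lapply(specs, run_scenario, params = params, ...)
  table <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario_id = r$scenario_id,
               delta_cost = r$delta_cost,
               delta_qalys = r$delta_qalys,
               icer = r$icer_value,
               label = r$dominance_label,
               strict = if (is.na(r$strict)) NA else r$strict,
               stringsAsFactors = FALSE)
  }))
  rownames(table) <- NULL
  list(results = results, table = table)
}
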