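#' Published one-way sensitivity bounds
#'
#' The deterministic sensitivity analysis (DSA) bound set: each entry
#' names a parameter, its low and high value, and carries the
#' recomposition rule (`apply`) that maps a swept value back into a
#' structurally valid parameter ledger. Costs whose published bounds are
#' generated by a composition (app reimbursement price, number of
#' physiotherapy sessions, daily wage) are recomposed through
#' [treatment_entry_cost()], [physiotherapy_cycle_cost()] and the
#' first-treatment-month wage component; probability bounds published on
#' the raw scale (treatment entry, remission share of dropouts,
#' remission persistence) are recomposed into full rows before matrix
#' construction.
#'
#' @param params Base parameter ledger the bounds attach to.
#' @return Named list of `lbp_dsa_bound` objects (fields `parameter_id`,
#'   `low`, `high`, `base`, `apply`).
#' @export
dsa_bounds <- function(params = base_parameters()) {
  uc <- params$unit_costs
  wage <- daily_wage(uc$monthly_gross_wage, uc$working_days_per_month)

  bound <- function(parameter_id, low, high, base, apply) {
    if (low > high) {
      stop(sprintf("dsa bound %s: low > high", parameter_id), call. = FALSE)
    }
    structure(list(parameter_id = parameter_id, low = low, high = high,
                   base = base, apply = apply),
              class = "lbp_dsa_bound")
  }

  set_state_cost <- function(p, state, value, strategies = lbp_strategies()) {
    for (s in strategies) p$state_costs[[s]][[state]] <- value
    p
  }

  list(
    app_price = bound("app_price", 99.96, 299.96, uc$app_price,
      function(p, v) {
        p$unit_costs$app_price <- v
        # recomposition uses the *base* ledger so the base program
        # component stays the published one
        set_state_cost(p, "T_W1_4", treatment_entry_cost("DTC", v, params), "DTC")
      }),
    physio_sessions = bound("physio_sessions", 4, 12, uc$physio_sessions,
      function(p, v) {
        p$unit_costs$physio_sessions <- v
        block <- physiotherapy_cycle_cost(v, uc$physio_session,
                                          uc$prescription_charge, uc$copay_rate)
        set_state_cost(p, "T_W1_4", treatment_entry_cost("TAU", block, params), "TAU")
      }),
    daily_wage = bound("daily_wage", 132.52, 161.96, wage,
      function(p, v) {
        # one day of absenteeism is bundled into each first-treatment-month
        # state cost; substitute the wage component there
        for (s in lbp_strategies()) {
          p$state_costs[[s]][["T_W1_4"]] <-
            round_cents(params$state_costs[[s]][["T_W1_4"]] - wage + v)
        }
        p
      }),
    low_state_cost = bound("low_state_cost", 397.55, 530.06,
      params$state_costs$DTC[["LOW"]],
      function(p, v) set_state_cost(p, "LOW", v)),
    high_state_cost = bound("high_state_cost", 471.17, 706.75,
      params$state_costs$DTC[["HIGH"]],
      function(p, v) set_state_cost(p, "HIGH", v)),
    discount_rate = bound("discount_rate", 0.00, 0.05,
      params$settings$discount_rate,
      function(p, v) { p$settings$discount_rate <- v; p }),
    low_to_treatment = bound("low_to_treatment", 0.60, 0.90,
      params$transitions$low_to_treatment,
      function(p, v) { p$transitions$low_to_treatment <- v; p }),
    high_to_treatment = bound("high_to_treatment", 0.70, 0.90,
      params$transitions$high_to_treatment,
      function(p, v) { p$transitions$high_to_treatment <- v; p }),
    remission_share = bound("remission_share", 0.40, 0.60,
      params$transitions$remission_share,
      function(p, v) {
        p$transitions$remission_share <- v
        for (s in lbp_strategies()) {
          p <- set_attrition(p, s, params$transitions$attrition[[s]],
                             remission_share = v)
        }
        p
      }),
    eot_to_remission = bound("eot_to_remission", 0.583, 0.644,
      params$transitions$end_row[["REMISSION"]],
      function(p, v) {
        p$transitions$end_row[["REMISSION"]] <- v
        p   # LOW/HIGH rebalanced by the end-of-treatment residual rule
      }),
    eot_to_healthy_dtc = bound("eot_to_healthy_dtc", 0.095, 0.105,
      params$transitions$end_to_healthy[["DTC"]],
      function(p, v) { p$transitions$end_to_healthy[["DTC"]] <- v; p }),
    eot_to_healthy_tau = bound("eot_to_healthy_tau", 0.0475, 0.0525,
      params$transitions$end_to_healthy[["TAU"]],
      function(p, v) { p$transitions$end_to_healthy[["TAU"]] <- v; p }),
    remission_stay = bound("remission_stay", 0.30, 0.46,
      params$transitions$remission_row[["REMISSION"]],
      function(p, v) {
        row <- params$transitions$remission_row
        lh <- row[c("LOW", "HIGH")] * (1 - v) / sum(row[c("LOW", "HIGH")])
        p$transitions$remission_row <- c(lh, REMISSION = v)
        p
      }),
    utility_high = bound("utility_high", 0.5795, 0.6405,
      params$utilities$DTC[["HIGH"]],
      function(p, v) {
        for (s in lbp_strategies()) p$utilities[[s]][["HIGH"]] <- v
        p
      }),
    utility_remission = bound("utility_remission", 0.7657, 0.8463,
      params$utilities$DTC[["REMISSION"]],
      function(p, v) {
        for (s in lbp_strategies()) p$utilities[[s]][["REMISSION"]] <- v
        p
      }),
    utility_healthy = bound("utility_healthy", 0.7657, 0.8463,
      params$utilities$DTC[["HEALTHY"]],
      function(p, v) {
        for (s in lbp_strategies()) p$utilities[[s]][["HEALTHY"]] <- v
        p
      })
  )
}

#' Signed ICER sentinel for tornado ordering
#'
#' Dominant outcomes carry no finite ICER; for ordering and plotting the
#' tornado, each incremental result is mapped to the signed ratio
#' `delta_cost / delta_qalys` (negative when the intervention dominates,
#' i.e. is cheaper and more effective), and to a signed infinite
#' sentinel when the effect difference is exactly zero.
#'
#' @param inc An `lbp_incremental`.
#' @return A single number.
#' @export
icer_sentinel <- function(inc) {
  stopifnot(inherits(inc, "lbp_incremental"))
  if (inc$delta_qalys == 0) {
    return(sign(inc$delta_cost) * Inf)
  }
  inc$delta_cost / inc$delta_qalys
}

#' One-way deterministic sensitivity analysis
#'
#' For each bound, reruns the full base-case pipeline with only that
#' parameter (plus its linked recompositions) set to its low and then
#' its high value, and records the resulting incremental outcome. Rows
#' come back in tornado order (descending sentinel range).
#'
#' @param params Base parameter ledger.
#' @param bounds List of `lbp_dsa_bound` objects (default
#'   [dsa_bounds()]).
#' @param ... Passed on to [run_scenario()] (residual policies).
#' @return An `lbp_dsa_table`: data.frame with one row per parameter
#'   (`parameter_id`, `low`, `high`, `icer_low`, `icer_high`,
#'   `label_low`, `label_high`, `range`), with the base-case
#'   `lbp_incremental` in the `"base"` attribute.
#' @export
one_way_dsa <- function(params, bounds = dsa_bounds(params), ...) {
  stopifnot(inherits(params, "lbp_parameters"))
  base_inc <- run_scenario(scenario_spec("base", params$settings$horizon_years),
                           params, ...)
  rows <- lapply(bounds, function(b) {
    if (!inherits(b, "lbp_dsa_bound")) {
      stop("one_way_dsa(): bounds must be lbp_dsa_bound objects", call. = FALSE)
    }
    at <- function(v) {
      p <- b$apply(params, v)
      run_scenario(scenario_spec(b$parameter_id, p$settings$horizon_years), p, ...)
    }
    lo <- at(b$low); hi <- at(b$high)
    s_lo <- icer_sentinel(lo); s_hi <- icer_sentinel(hi)
    data.frame(parameter_id = b$parameter_id, low = b$low, high = b$high,
               icer_low = s_lo, icer_high = s_hi,
               label_low = lo$dominance_label, label_high = hi$dominance_label,
               range = abs(s_hi - s_lo), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- structure(tab, class = c("lbp_dsa_table", "data.frame"),
                   base = base_inc)
  tornado_order(tab)
}

#' Order a DSA table for the tornado diagram
#'
#' Stable sort by descending sentinel range; ties broken by
#' `parameter_id` in lexicographic order.
#'
#' @param table An `lbp_dsa_table` (or data.frame with `range` and
#'   `parameter_id` columns).
#' @return The table, reordered.
#' @export
tornado_order <- function(table) {
  stopifnot(is.data.frame(table), all(c("range", "parameter_id") %in% names(table)))
  ord <- order(-table$range, table$parameter_id)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(table)
  attr(out, "base") <- attrs$base
  class(out) <- class(table)
  out
}

#' @export
print.lbp_dsa_table <- function(x, ...) {
  base <- attr(x, "base")
  cat("<lbp_dsa_table>")
  if (!is.null(base) && base$dominance_label == "ICER") {
    cat(sprintf(" base ICER %.0f EUR/QALY", base$icer_value))
  }
  cat("\n")
  print(as.data.frame(x), digits = 6)
  invisible(x)
}
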