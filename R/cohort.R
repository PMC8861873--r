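#' Per-cycle discount factor
#'
#' Discounting compounds continuously per cycle:
#' `(1 + annual_rate)^(-cycle_index / cycles_per_year)`; cycle 0 is
#' undiscounted.
#'
#' @param cycle_index Non-negative cycle index (vectorized).
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycles_per_year Model cycles per year (default 12, monthly
#'   cycles).
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(0, 0.03)       # 1
#' discount_factor(12, 0.03, 12)  # 1/1.03
#' @export
discount_factor <- function(cycle_index, annual_rate, cycles_per_year = 12) {
  if (any(cycle_index < 0)) {
    stop("discount_factor(): cycle_index must be non-negative", call. = FALSE)
  }
  if (annual_rate < 0) {
    stop("discount_factor(): annual_rate must be non-negative", call. = FALSE)
  }
  if (cycles_per_year < 1) {
    stop("discount_factor(): cycles_per_year must be at least 1", call. = FALSE)
  }
  (1 + annual_rate)^(-cycle_index / cycles_per_year)
}

#' Propagate a cohort through the Markov chain
#'
#' Deterministic cohort propagation: `raw[t + 1, ] = raw[t, ] %*% tm`.
#' The life-table (half-cycle) correction values each cycle at the
#' average of its start- and end-of-cycle state memberships:
#' `corrected[t] = (raw[t] + raw[t + 1]) / 2`.
#'
#' @param tm An `lbp_transition_matrix` (or plain 7x7 row-stochastic
#'   matrix with the state dimnames).
#' @param start Starting state vector (persons, length 7, >= 0).
#' @param n_cycles Number of cycles to run (>= 1).
#' @return An `lbp_cohort_trace`: list with `raw` ((n_cycles + 1) x 7),
#'   `corrected` (n_cycles x 7), `cohort_size` and `strategy`.
#' @export
run_cohort <- function(tm, start, n_cycles) {
  states <- lbp_states()
  if (!is.matrix(tm) || !all(dim(tm) == 7)) {
    stop("run_cohort(): tm must be a 7x7 matrix", call. = FALSE)
  }
  if (length(start) != 7) {
    stop("run_cohort(): start must have length 7", call. = FALSE)
  }
  if (any(start < 0)) {
    stop("run_cohort(): start entries must be non-negative", call. = FALSE)
  }
  if (n_cycles < 1) {
    stop("run_cohort(): n_cycles must be at least 1", call. = FALSE)
  }
  raw <- matrix(0, n_cycles + 1, 7, dimnames = list(0:n_cycles, states))
  raw[1, ] <- as.numeric(start)
  M <- unclass(tm)
  for (t in seq_len(n_cycles)) {
    raw[t + 1, ] <- raw[t, ] %*% M
  }
  corrected <- (raw[seq_len(n_cycles), , drop = FALSE] +
                raw[seq_len(n_cycles) + 1, , drop = FALSE]) / 2
  rownames(corrected) <- seq_len(n_cycles) - 1
  structure(list(raw = raw, corrected = corrected,
                 cohort_size = sum(start),
                 strategy = attr(tm, "strategy")),
            class = "lbp_cohort_trace")
}

#' @export
print.lbp_cohort_trace <- function(x, ...) {
  n <- nrow(x$raw) - 1
  cat(sprintf("<lbp_cohort_trace> %s: %d cycles, cohort %.0f\n",
              x$strategy %||% "?", n, x$cohort_size))
  cat("  final membership:\n")
  print(round(x$raw[n + 1, ], 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-state value schedule for a strategy
#'
#' Bundles the per-state cycle costs (EUR) and quality-of-life utilities
#' (annual QALY weights) for one strategy, together with the cycle
#' length in years, ready for [accrue_values()].
#'
#' @param params Parameter ledger.
#' @param strategy `"DTC"` or `"TAU"`.
#' @return An `lbp_value_schedule` list with `costs`, `utilities`,
#'   `cycle_length_years` and `strategy`.
#' @export
value_schedule <- function(params, strategy) {
  stopifnot(inherits(params, "lbp_parameters"))
  strategy <- match.arg(strategy, lbp_strategies())
  util <- params$utilities[[strategy]][lbp_states()]
  cost <- params$state_costs[[strategy]][lbp_states()]
  if (any(util < 0) || any(util > 1)) {
    stop("value_schedule(): utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cost < 0)) {
    stop("value_schedule(): state costs must be non-negative", call. = FALSE)
  }
  structure(list(costs = cost, utilities = util,
                 cycle_length_years = 1 / params$settings$cycles_per_year,
                 strategy = strategy),
            class = "lbp_value_schedule")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Each cycle's accrual multiplies the life-table-corrected state
#' membership by the per-state value (cost as-is; utility times the
#' cycle length in years) and discounts it at the cycle's start-index
#' factor. Totals are divided by the cohort size to give per-person
#' values. The same correction and discounting are applied to costs and
#' QALYs.
#'
#' @param trace An `lbp_cohort_trace`.
#' @param schedule An `lbp_value_schedule`.
#' @param annual_rate Annual discount rate (default 0.03).
#' @return An `lbp_strategy_totals` list: per-person `discounted_cost`,
#'   `discounted_qalys` and undiscounted variants, per-state 7-vector
#'   breakdowns, `healthy_at_horizon` (raw final-cycle HEALTHY
#'   membership, rounded half-up to a whole person) and bookkeeping
#'   fields (`horizon_years`, `cohort_size`, `strategy`).
#' @export
accrue_values <- function(trace, schedule, annual_rate = 0.03) {
  stopifnot(inherits(trace, "lbp_cohort_trace"),
            inherits(schedule, "lbp_value_schedule"))
  n_cycles <- nrow(trace$corrected)
  cycles_per_year <- 1 / schedule$cycle_length_years
  df <- discount_factor(seq_len(n_cycles) - 1, annual_rate, cycles_per_year)
  occ_disc <- trace$corrected * df         # recycles df down columns
  per_state <- function(occ, values, scale) colSums(occ) * values * scale
  n <- trace$cohort_size
  per_state_cost <- per_state(occ_disc, schedule$costs, 1) / n
  per_state_qalys <- per_state(occ_disc, schedule$utilities,
                               schedule$cycle_length_years) / n
  per_state_cost_undisc <- per_state(trace$corrected, schedule$costs, 1) / n
  per_state_qalys_undisc <- per_state(trace$corrected, schedule$utilities,
                                      schedule$cycle_length_years) / n
  healthy_final <- trace$raw[n_cycles + 1, "HEALTHY"]
  structure(list(
    strategy = schedule$strategy,
    discounted_cost = sum(per_state_cost),
    discounted_qalys = sum(per_state_qalys),
    undiscounted_cost = sum(per_state_cost_undisc),
    undiscounted_qalys = sum(per_state_qalys_undisc),
    per_state_cost = per_state_cost,
    per_state_qalys = per_state_qalys,
    healthy_at_horizon = floor(healthy_final + 0.5),
    horizon_years = n_cycles / cycles_per_year,
    cohort_size = n,
    discount_rate = annual_rate
  ), class = "lbp_strategy_totals")
}

#' @export
print.lbp_strategy_totals <- function(x, ...) {
  cat(sprintf("<lbp_strategy_totals> %s over %g y (discount %.1f%%)\n",
              x$strategy, x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  cost  %10.2f EUR/person (undiscounted %.2f)\n",
              x$discounted_cost, x$undiscounted_cost))
  cat(sprintf("  QALYs %10.4f per person (undiscounted %.4f)\n",
              x$discounted_qalys, x$undiscounted_qalys))
  cat(sprintf("  healthy at horizon: %d persons\n", x$healthy_at_horizon))
  invisible(x)
}

#' Run one strategy end to end
#'
#' Convenience wrapper: builds the transition matrix, propagates the
#' starting cohort over the horizon, and accrues discounted values.
#'
#' @param params Parameter ledger.
#' @param strategy `"DTC"` or `"TAU"`.
#' @param horizon_years Model horizon in years (default from `params`).
#' @param discount_rate Annual discount rate (default from `params`).
#' @inheritParams build_transition_matrix
#' @return A list with components `totals` (`lbp_strategy_totals`),
#'   `trace` (`lbp_cohort_trace`) and `matrix`
#'   (`lbp_transition_matrix`).
#' @examples
#' run_strategy(base_parameters(), "DTC")$totals
#' @export
run_strategy <- function(params, strategy,
                         horizon_years = params$settings$horizon_years,
                         discount_rate = params$settings$discount_rate,
                         residual_policy = "renormalize_non_treatment",
                         eot_residual = "trajectory_split") {
  tm <- build_transition_matrix(params, strategy,
                                residual_policy = residual_policy,
                                eot_residual = eot_residual)
  n_cycles <- round(horizon_years * params$settings$cycles_per_year)
  trace <- run_cohort(tm, start_vector(params), n_cycles)
  totals <- accrue_values(trace, value_schedule(params, strategy), discount_rate)
  list(totals = totals, trace = trace, matrix = tm)
}
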