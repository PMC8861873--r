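#' Ordered state space of the low back pain model
#'
#' Seven discrete health states: untreated low-impact and high-impact LBP,
#' three one-month treatment tunnel states (weeks 1-4, 4-8 and 8-12 of a
#' 12-week program), temporary remission, and an absorbing healthy state
#' (no recurrence within the model horizon). The order is fixed; every
#' matrix, trace and value schedule in the package uses it.
#'
#' @return Character vector of the seven state labels.
#' @export
lbp_states <- function() {
  c("LOW", "HIGH", "T_W1_4", "T_W4_8", "T_W8_12", "REMISSION", "HEALTHY")
}

#' @rdname lbp_states
#' @return `lbp_absorbing()` returns a named logical vector flagging the
#'   absorbing state (HEALTHY only).
#' @export
lbp_absorbing <- function() {
  stats::setNames(lbp_states() == "HEALTHY", lbp_states())
}

#' Strategy labels
#'
#' `"DTC"` is the digital therapeutic care app strategy (3-month app
#' prescription), `"TAU"` is treatment as usual (six face-to-face
#' physiotherapy sessions).
#'
#' @return Character vector of the two strategy labels.
#' @export
lbp_strategies <- function() c("DTC", "TAU")

#' Base-case model parameter ledger
#'
#' Returns the complete parameter set of the German DTC-versus-TAU
#' cost-utility evaluation that this package re-implements: transition
#' inputs, per-state quality-of-life utilities, unit costs and per-state
#' cycle costs (2021 Euro), the discount rate, the model horizon and the
#' starting cohort. All values are the final calculated model inputs at
#' their published precision; derived unit costs (physiotherapy cycle
#' cost, daily wage, treatment-entry costs) can be recomposed from the
#' unit-cost primitives via [physiotherapy_cycle_cost()], [daily_wage()]
#' and [treatment_entry_cost()].
#'
#' Monthly model cycles are used (12 cycles per year; the three treatment
#' tunnel states correspond to the three months of a 12-week program), so
#' the default 3-year horizon is 36 cycles.
#'
#' @return An object of class `lbp_parameters`: a named nested list with
#'   components `meta`, `settings`, `transitions`, `utilities`,
#'   `unit_costs` and `state_costs`. Treat it as immutable; derive
#'   modified copies with [set_attrition()] or the sensitivity-analysis
#'   bound machinery rather than editing slots.
#' @seealso [load_parameters()], [write_parameters()], [dsa_bounds()]
#' @examples
#' p <- base_parameters()
#' p$utilities$DTC[["T_W8_12"]]   # 0.748
#' p$state_costs$TAU[["T_W1_4"]]  # 377.85
#' @export
base_parameters <- function() {
  states <- lbp_states()
  out <- list(
    meta = list(
      schema_version = "1.0",
      currency = "EUR-2021",
      note = paste(
        "DTC app reimbursement price carried at 239.96, the only value",
        "consistent with the 475.08 first-treatment-cycle state cost;",
        "alternative published figures (296/296.99) refer to a later",
        "price level and are not used."
      )
    ),
    settings = list(
      cohort_size = 10000,
      # starting distribution over LOW / HIGH / REMISSION
      start = c(LOW = 5320, HIGH = 1120, REMISSION = 3560),
      discount_rate = 0.03,
      cycles_per_year = 12,
      horizon_years = 3
    ),
    transitions = list(
      # untreated rows: printed destinations; the treatment-entry
      # probability is held separately because it is an explicit
      # assumption (75% / 80%) and must stay fixed when residual row
      # mass is resolved (see build_transition_matrix()).
      low_row = c(LOW = 0.16, HIGH = 0.01, REMISSION = 0.03),
      low_to_treatment = 0.75,
      high_row = c(LOW = 0.02, HIGH = 0.08),
      high_to_treatment = 0.80,
      # treatment tunnel rows as final published inputs (4 decimals);
      # CONTINUE is the transition to the next tunnel state.
      treatment_rows = list(
        DTC = list(
          w1_4 = c(LOW = 0.0514, HIGH = 0.0111, CONTINUE = 0.875, REMISSION = 0.0625),
          w4_8 = c(LOW = 0.0514, HIGH = 0.0111, CONTINUE = 0.875, REMISSION = 0.0625)
        ),
        TAU = list(
          w1_4 = c(LOW = 0.0267, HIGH = 0.0058, CONTINUE = 0.935, REMISSION = 0.0325),
          w4_8 = c(LOW = 0.0177, HIGH = 0.0038, CONTINUE = 0.957, REMISSION = 0.0215)
        )
      ),
      # monthly attrition underlying the tunnel rows (month 1 -> 2,
      # month 2 -> 3); kept for scenario recomposition via dropout_split()
      attrition = list(DTC = c(0.125, 0.125), TAU = c(0.065, 0.043)),
      remission_share = 0.5,
      low_trajectory_share = 0.822,
      # end-of-treatment row (week 8-12 completers); HEALTHY entry is
      # strategy specific (+0.05 for DTC, the app's behaviour-change
      # advantage)
      end_row = c(LOW = 0.235, HIGH = 0.051, REMISSION = 0.614),
      end_to_healthy = c(DTC = 0.10, TAU = 0.05),
      remission_row = c(LOW = 0.505, HIGH = 0.109, REMISSION = 0.386)
    ),
    utilities = list(
      DTC = c(LOW = 0.655, HIGH = 0.610, T_W1_4 = 0.655, T_W4_8 = 0.699,
              T_W8_12 = 0.748, REMISSION = 0.806, HEALTHY = 0.806),
      TAU = c(LOW = 0.655, HIGH = 0.610, T_W1_4 = 0.655, T_W4_8 = 0.717,
              T_W8_12 = 0.729, REMISSION = 0.806, HEALTHY = 0.806)
    ),
    unit_costs = list(
      app_price = 239.96,           # one-time 3-month app access
      gp_consultation = 20.47,
      specialist_consultation = 21.36,
      physio_session = 21.11,
      physio_sessions = 6,          # sessions per TAU treatment entry
      prescription_charge = 10.00,  # one-time physiotherapy copayment
      copay_rate = 0.10,            # own share per physiotherapy session
      pharmacotherapy = 16.81,      # per cycle
      diagnostics = 29.24,          # per cycle (imaging at re-entry)
      monthly_gross_wage = 3092,
      working_days_per_month = 21
    ),
    state_costs = list(
      DTC = c(LOW = 441.72, HIGH = 588.96, T_W1_4 = 475.08, T_W4_8 = 16.81,
              T_W8_12 = 16.81, REMISSION = 0, HEALTHY = 0),
      TAU = c(LOW = 441.72, HIGH = 588.96, T_W1_4 = 377.85, T_W4_8 = 16.81,
              T_W8_12 = 16.81, REMISSION = 0, HEALTHY = 0)
    )
  )
  structure(out, class = "lbp_parameters")
}

#' @export
print.lbp_parameters <- function(x, ...) {
  s <- x$settings
  cat("<lbp_parameters> schema", x$meta$schema_version, "\n")
  cat(sprintf("  cohort %d (LOW %d / HIGH %d / REMISSION %d)\n",
              s$cohort_size, s$start[["LOW"]], s$start[["HIGH"]],
              s$start[["REMISSION"]]))
  cat(sprintf("  horizon %g y, %d cycles/y, discount %.1f%%/y\n",
              s$horizon_years, s$cycles_per_year, 100 * s$discount_rate))
  cat(sprintf("  attrition DTC %.3f/%.3f, TAU %.3f/%.3f\n",
              x$transitions$attrition$DTC[1], x$transitions$attrition$DTC[2],
              x$transitions$attrition$TAU[1], x$transitions$attrition$TAU[2]))
  invisible(x)
}

#' Starting cohort as a full state vector
#'
#' @param params An `lbp_parameters` object.
#' @return Named numeric vector over the seven states (persons).
#' @export
start_vector <- function(params) {
  stopifnot(inherits(params, "lbp_parameters"))
  v <- stats::setNames(numeric(7), lbp_states())
  st <- params$settings$start
  v[names(st)] <- st
  v
}

round_cents <- function(x) {
  # round half up to cents, matching every published derived cost
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

#' Split a treatment attrition rate over dropout destinations
#'
#' Patients leaving a treatment program before completion either enter
#' temporary remission (a `remission_share` fraction of dropouts,
#' reflecting spontaneous symptom relief) or fall back into untreated
#' LBP, split between the low- and high-impact trajectories in fixed
#' proportions (pain trajectories are stable over time, so prior
#' low-impact patients return to low impact).
#'
#' @param attrition Per-cycle probability of quitting the program.
#' @param remission_share Fraction of dropouts entering remission
#'   (default 0.5).
#' @param low_trajectory_share Fraction of non-remission dropouts
#'   returning to low-impact LBP (default 0.822).
#' @return A list with components `continue`, `to_remission`, `to_low`
#'   and `to_high`; the four probabilities sum to 1.
#' @examples
#' # app strategy, 12.5% monthly attrition
#' unlist(dropout_split(0.125))
#' @export
dropout_split <- function(attrition, remission_share = 0.5,
                          low_trajectory_share = 0.822) {
  for (p in c(attrition, remission_share, low_trajectory_share)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("dropout_split(): all inputs must be probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  nonrem <- attrition * (1 - remission_share)
  list(
    continue = 1 - attrition,
    to_remission = attrition * remission_share,
    to_low = nonrem * low_trajectory_share,
    to_high = nonrem * (1 - low_trajectory_share)
  )
}

#' Physiotherapy cost per treatment cycle
#'
#' Cost of a prescribed block of face-to-face physiotherapy sessions,
#' including the statutory patient copayments: a one-time prescription
#' charge plus an own share on every session.
#'
#' @param n_sessions Number of sessions in the prescription (>= 1).
#' @param session_price Price per session in EUR.
#' @param prescription_charge One-time prescription charge in EUR.
#' @param copay_rate Patient own-share fraction per session.
#' @return Cost in EUR, rounded half-up to cents.
#' @examples
#' physiotherapy_cycle_cost(6, 21.11, 10, 0.10)  # 149.33
#' @export
physiotherapy_cycle_cost <- function(n_sessions, session_price = 21.11,
                                     prescription_charge = 10.00,
                                     copay_rate = 0.10) {
  if (n_sessions < 1) {
    stop("physiotherapy_cycle_cost(): a prescription implies at least one session",
         call. = FALSE)
  }
  if (session_price < 0 || prescription_charge < 0 || copay_rate < 0) {
    stop("physiotherapy_cycle_cost(): prices must be non-negative", call. = FALSE)
  }
  round_cents(n_sessions * session_price * (1 + copay_rate) + prescription_charge)
}

#' Gross daily wage (human capital approach)
#'
#' Productivity losses from absenteeism are valued at the average gross
#' daily wage, i.e. monthly gross wage divided by working days per month.
#'
#' @param monthly_gross Monthly gross wage in EUR.
#' @param working_days Working days per month (>= 1).
#' @return Daily wage in EUR, rounded half-up to cents.
#' @examples
#' daily_wage(3092, 21)  # 147.24
#' @export
daily_wage <- function(monthly_gross = 3092, working_days = 21) {
  if (working_days < 1) {
    stop("daily_wage(): working_days must be at least 1", call. = FALSE)
  }
  if (monthly_gross < 0) {
    stop("daily_wage(): monthly_gross must be non-negative", call. = FALSE)
  }
  round_cents(monthly_gross / working_days)
}

#' Recompose the first-treatment-cycle state cost for a new program price
#'
#' The cost of the first treatment month bundles the treatment-program
#' component (the 3-month app price for DTC; the six-session
#' physiotherapy block for TAU) with consultations, pharmacotherapy,
#' diagnostics and one day of absenteeism. When a sensitivity analysis
#' varies only the program component, the state cost is recomposed as
#' base state cost minus base program component plus the new one.
#'
#' @param strategy `"DTC"` or `"TAU"`.
#' @param program_cost New program component in EUR (app price for DTC,
#'   physiotherapy block cost for TAU).
#' @param params Parameter ledger supplying the base state cost and base
#'   program components.
#' @return Recomposed T_W1_4 state cost in EUR, rounded to cents.
#' @examples
#' treatment_entry_cost("DTC", 99.96, base_parameters())   # 335.08
#' treatment_entry_cost("TAU", 288.65, base_parameters())  # 517.17
#' @export
treatment_entry_cost <- function(strategy, program_cost, params = base_parameters()) {
  strategy <- match.arg(strategy, lbp_strategies())
  if (program_cost < 0) {
    stop("treatment_entry_cost(): program_cost must be non-negative", call. = FALSE)
  }
  base_component <- if (strategy == "DTC") {
    params$unit_costs$app_price
  } else {
    physiotherapy_cycle_cost(params$unit_costs$physio_sessions,
                             params$unit_costs$physio_session,
                             params$unit_costs$prescription_charge,
                             params$unit_costs$copay_rate)
  }
  round_cents(params$state_costs[[strategy]][["T_W1_4"]] - base_component + program_cost)
}

#' Replace one strategy's treatment attrition rates
#'
#' Recomposes the two treatment tunnel rows of `strategy` from new
#' monthly attrition rates via [dropout_split()] (unrounded), leaving
#' everything else in the ledger untouched. This is the mechanism behind
#' the attrition scenarios.
#'
#' @param params Parameter ledger.
#' @param strategy `"DTC"` or `"TAU"`.
#' @param attrition Numeric vector of length 2: attrition after month
#'   one and after month two.
#' @inheritParams dropout_split
#' @return A modified copy of `params`.
#' @export
set_attrition <- function(params, strategy, attrition,
                          remission_share = params$transitions$remission_share,
                          low_trajectory_share = params$transitions$low_trajectory_share) {
  stopifnot(inherits(params, "lbp_parameters"), length(attrition) == 2)
  strategy <- match.arg(strategy, lbp_strategies())
  rows <- lapply(attrition, function(a) {
    s <- dropout_split(a, remission_share, low_trajectory_share)
    c(LOW = s$to_low, HIGH = s$to_high, CONTINUE = s$continue,
      REMISSION = s$to_remission)
  })
  params$transitions$treatment_rows[[strategy]] <-
    list(w1_4 = rows[[1]], w4_8 = rows[[2]])
  params$transitions$attrition[[strategy]] <- attrition
  params
}
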