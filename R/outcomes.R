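#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies an (incremental cost, incremental effect) pair on the
#' cost-effectiveness plane:
#'
#' * NE quadrant (costlier, more effective): `"ICER"` with value
#'   `delta_cost / delta_qalys`;
#' * SE (cheaper, more effective): `"intervention_dominant"`;
#' * NW (costlier, less effective): `"comparator_dominant"` with
#'   `strict = TRUE`;
#' * SW (cheaper, less effective): `"comparator_dominant"` with
#'   `strict = FALSE` — labelled after the reporting convention of the
#'   reference analysis, although strict dominance does not hold there;
#' * zero effect difference with non-zero cost difference:
#'   `"undefined_ratio"` (a signal, not an error); both zero:
#'   `"indeterminate"`.
#'
#' @param delta_cost Incremental cost (EUR per person).
#' @param delta_qalys Incremental effect (QALYs per person).
#' @return List with `value` (EUR/QALY, `NA` unless the label is
#'   `"ICER"`), `label`, and `strict` (logical, meaningful for
#'   comparator dominance).
#' @examples
#' icer(121.59, 0.0221)
#' icer(-288.58, 0.0319)  # intervention dominant
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) {
    if (delta_cost == 0) {
      return(list(value = NA_real_, label = "indeterminate", strict = NA))
    }
    return(list(value = NA_real_, label = "undefined_ratio", strict = NA))
  }
  if (delta_qalys > 0) {
    if (delta_cost > 0) {
      return(list(value = delta_cost / delta_qalys, label = "ICER", strict = NA))
    }
    if (delta_cost < 0) {
      return(list(value = NA_real_, label = "intervention_dominant", strict = TRUE))
    }
    # equal cost, more effect: weakly dominant intervention
    return(list(value = NA_real_, label = "intervention_dominant", strict = FALSE))
  }
  # delta_qalys < 0
  list(value = NA_real_, label = "comparator_dominant", strict = delta_cost >= 0)
}

#' Incremental outcomes between two strategies
#'
#' Differences are taken on unrounded internals (intervention minus
#' comparator) and the ICER is computed before any rounding.
#'
#' @param intervention,comparator `lbp_strategy_totals` computed on the
#'   same horizon and discount rate.
#' @param scenario_id Label attached to the result.
#' @return An `lbp_incremental` list: `delta_cost`, `delta_qalys`,
#'   `icer_value` (`NA` unless classified as an ICER), `dominance_label`,
#'   `strict`, `scenario_id`, plus the two strategy labels.
#' @export
incremental_outcomes <- function(intervention, comparator, scenario_id = "base") {
  stopifnot(inherits(intervention, "lbp_strategy_totals"),
            inherits(comparator, "lbp_strategy_totals"))
  if (abs(intervention$horizon_years - comparator$horizon_years) > 1e-9 ||
      abs(intervention$discount_rate - comparator$discount_rate) > 1e-12) {
    stop("incremental_outcomes(): totals must share horizon and discount rate",
         call. = FALSE)
  }
  dc <- intervention$discounted_cost - comparator$discounted_cost
  dq <- intervention$discounted_qalys - comparator$discounted_qalys
  cls <- icer(dc, dq)
  structure(list(
    scenario_id = scenario_id,
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    delta_cost = dc,
    delta_qalys = dq,
    icer_value = cls$value,
    dominance_label = cls$label,
    strict = cls$strict
  ), class = "lbp_incremental")
}

#' @export
print.lbp_incremental <- function(x, ...) {
  cat(sprintf("<lbp_incremental> %s: %s vs %s\n", x$scenario_id,
              x$intervention %||% "?", x$comparator %||% "?"))
  cat(sprintf("  dCost %.2f EUR, dQALY %.4f\n", x$delta_cost, x$delta_qalys))
  if (x$dominance_label == "ICER") {
    cat(sprintf("  ICER %.2f EUR/QALY\n", x$icer_value))
  } else {
    flag <- if (isFALSE(x$strict)) " (non-strict)" else ""
    cat(sprintf("  %s%s\n", x$dominance_label, flag))
  }
  invisible(x)
}

#' Annualize strategy totals
#'
#' @param totals An `lbp_strategy_totals`.
#' @param horizon_years Years to divide by (defaults to the totals' own
#'   horizon).
#' @return List with `cost_per_year` and `qalys_per_year`, per person.
#' @export
annualize <- function(totals, horizon_years = totals$horizon_years) {
  stopifnot(inherits(totals, "lbp_strategy_totals"), horizon_years >= 1)
  list(cost_per_year = totals$discounted_cost / horizon_years,
       qalys_per_year = totals$discounted_qalys / horizon_years)
}

#' Health care resource utilization summaries
#'
#' Counts primary care consultations and treatment prescriptions implied
#' by a cohort trace under a documented convention: each person-cycle
#' spent in a consultation-incurring state (untreated LOW/HIGH, or the
#' first treatment month) generates `gp_contacts` general-practitioner
#' and `specialist_contacts` specialist contacts; a prescription (app or
#' physiotherapy block) is counted for every entry into the first
#' treatment state. The convention is returned alongside the numbers and
#' is a modelling choice, not an estimated quantity.
#'
#' @param trace An `lbp_cohort_trace`.
#' @param params Parameter ledger (supplies the horizon bookkeeping).
#' @param gp_contacts,specialist_contacts Contacts per person-cycle in a
#'   consultation-incurring state.
#' @return List with `consultations_per_year`, `prescriptions_total`,
#'   `person_cycles` and `convention`.
#' @export
resource_utilization <- function(trace, params, gp_contacts = 1,
                                 specialist_contacts = 1) {
  stopifnot(inherits(trace, "lbp_cohort_trace"),
            inherits(params, "lbp_parameters"))
  n_cycles <- nrow(trace$corrected)
  years <- n_cycles / params$settings$cycles_per_year
  states <- c("LOW", "HIGH", "T_W1_4")
  person_cycles <- sum(trace$corrected[, states])
  consultations <- person_cycles * (gp_contacts + specialist_contacts)
  # T_W1_4 has no self-loop and is entered only from LOW/HIGH, so the
  # raw membership at each cycle end equals the new entries that cycle
  prescriptions <- sum(trace$raw[-1, "T_W1_4"])
  list(
    consultations_per_year = consultations / years,
    prescriptions_total = prescriptions,
    person_cycles = person_cycles,
    convention = sprintf(
      "%g GP + %g specialist contact(s) per person-cycle in LOW/HIGH/T_W1_4; one prescription per entry into T_W1_4",
      gp_contacts, specialist_contacts)
  )
}

#' Cost-effectiveness plane export
#'
#' One point per incremental result, plus willingness-to-pay threshold
#' lines (EUR/QALY slopes through the origin).
#'
#' @param results List of `lbp_incremental` objects.
#' @param thresholds Threshold slopes in EUR per QALY.
#' @return List with `points` (data.frame: `scenario_id`, `delta_qalys`,
#'   `delta_cost`, `label`) and `thresholds` (data.frame: `threshold`).
#' @export
ce_plane_points <- function(results, thresholds = c(10000, 20000)) {
  pts <- if (length(results) == 0) {
    data.frame(scenario_id = character(0), delta_qalys = numeric(0),
               delta_cost = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(results, function(r) {
      stopifnot(inherits(r, "lbp_incremental"))
      data.frame(scenario_id = r$scenario_id, delta_qalys = r$delta_qalys,
                 delta_cost = r$delta_cost, label = r$dominance_label,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(pts) <- NULL
  list(points = pts, thresholds = data.frame(threshold = thresholds))
}
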