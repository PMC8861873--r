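#' Write a parameter ledger to a YAML configuration file
#'
#' The configuration mirrors the ledger structure one-to-one (sections
#' `meta`, `settings`, `transitions`, `utilities`, `unit_costs`,
#' `state_costs`) and round-trips exactly through [load_parameters()].
#'
#' @param params An `lbp_parameters` ledger.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "lbp_parameters"))
  # shortest decimal that parses back to the identical double, so the
  # file stays human-readable and the round trip stays exact
  fmt <- function(x) {
    for (dg in 1:17) {
      s <- format(x, digits = dg, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == x) return(structure(s, class = "verbatim"))
    }
    structure(format(x, digits = 18, scientific = FALSE, trim = TRUE),
              class = "verbatim")
  }
  # named numeric vectors must become YAML maps, not bare sequences
  mapify <- function(x) {
    if (is.list(x)) return(lapply(x, mapify))
    if (is.numeric(x) && length(x) == 1 && is.null(names(x))) return(fmt(x))
    if (is.atomic(x) && !is.null(names(x))) return(lapply(as.list(x), mapify))
    if (is.numeric(x)) return(lapply(as.list(x), fmt))
    x
  }
  yaml::write_yaml(mapify(unclass(params)), path)
  invisible(path)
}

config_schema <- function() {
  list(
    meta = c("schema_version", "currency", "note"),
    settings = c("cohort_size", "start", "discount_rate", "cycles_per_year",
                 "horizon_years"),
    transitions = c("low_row", "low_to_treatment", "high_row",
                    "high_to_treatment", "treatment_rows", "attrition",
                    "remission_share", "low_trajectory_share", "end_row",
                    "end_to_healthy", "remission_row"),
    utilities = c("DTC", "TAU"),
    unit_costs = c("app_price", "gp_consultation", "specialist_consultation",
                   "physio_session", "physio_sessions", "prescription_charge",
                   "copay_rate", "pharmacotherapy", "diagnostics",
                   "monthly_gross_wage", "working_days_per_month"),
    state_costs = c("DTC", "TAU")
  )
}

#' Load and validate a parameter ledger from a YAML file
#'
#' Unknown keys are rejected, missing keys reported by name, and
#' probability-valued fields checked against \[0, 1\].
#'
#' @param path Path to a YAML file written by [write_parameters()] (or
#'   hand-edited in the same layout).
#' @return An `lbp_parameters` ledger.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("load_parameters(): no such file: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  schema <- config_schema()

  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    stop(sprintf("load_parameters(): unknown section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (sec in names(schema)) {
    if (is.null(raw[[sec]])) {
      stop(sprintf("load_parameters(): missing section '%s'", sec), call. = FALSE)
    }
    missing_keys <- setdiff(schema[[sec]], names(raw[[sec]]))
    if (length(missing_keys)) {
      stop(sprintf("load_parameters(): section '%s' is missing key(s): %s",
                   sec, paste(missing_keys, collapse = ", ")), call. = FALSE)
    }
    unknown_keys <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(unknown_keys)) {
      stop(sprintf("load_parameters(): section '%s' has unknown key(s): %s",
                   sec, paste(unknown_keys, collapse = ", ")), call. = FALSE)
    }
  }

  num_vec <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  p <- raw
  # YAML has no integer/double distinction that matters here: carry all
  # numeric scalars as doubles so a written ledger reloads identically
  p$settings <- lapply(p$settings, function(x) {
    if (is.numeric(x) || is.list(x)) num_vec(x) else x
  })
  p$unit_costs <- lapply(p$unit_costs, function(x) as.numeric(x))
  p$settings$start <- num_vec(p$settings$start)
  tr <- p$transitions
  for (f in c("low_row", "high_row", "end_row", "end_to_healthy",
              "remission_row")) {
    tr[[f]] <- num_vec(tr[[f]])
  }
  tr$treatment_rows <- lapply(tr$treatment_rows, function(s) lapply(s, num_vec))
  tr$attrition <- lapply(tr$attrition, num_vec)
  p$transitions <- tr
  p$utilities <- lapply(p$utilities, num_vec)
  p$state_costs <- lapply(p$state_costs, num_vec)
  params <- structure(p, class = "lbp_parameters")

  check01 <- function(x, where) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(sprintf("load_parameters(): probability outside [0, 1] in %s", where),
           call. = FALSE)
    }
  }
  check01(c(tr$low_row, tr$low_to_treatment, tr$high_row, tr$high_to_treatment,
            tr$end_row, tr$end_to_healthy, tr$remission_row,
            unlist(tr$treatment_rows), unlist(tr$attrition),
            tr$remission_share, tr$low_trajectory_share), "transitions")
  check01(unlist(params$utilities), "utilities")
  check01(params$settings$discount_rate, "settings$discount_rate")
  if (any(unlist(params$state_costs) < 0) ||
      any(unlist(params$unit_costs) < 0)) {
    stop("load_parameters(): costs must be non-negative", call. = FALSE)
  }
  if (abs(sum(params$settings$start) - params$settings$cohort_size) > 1e-9) {
    stop("load_parameters(): start distribution must sum to cohort_size",
         call. = FALSE)
  }
  params
}
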