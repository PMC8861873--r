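#' Build a strategy's transition matrix
#'
#' Assembles the row-stochastic 7x7 transition matrix over
#' [lbp_states()] for one strategy. The published inputs leave some row
#' mass unallocated (the LOW row sums to 0.95, the HIGH row to 0.90,
#' and TAU's end-of-treatment row to 0.95); the residual mass is
#' resolved by an explicit, recorded policy:
#'
#' * `residual_policy` (untreated LOW/HIGH rows):
#'   `"renormalize_non_treatment"` (default) keeps the treatment-entry
#'   probability fixed at its stated assumption (0.75 / 0.80) and scales
#'   the remaining destinations proportionally so the row sums to 1;
#'   `"self_loop"` adds the deficit to the stay-put probability.
#' * `eot_residual` (end-of-treatment row): `"trajectory_split"`
#'   (default) assigns any deficit to the untreated LOW/HIGH states in
#'   the 82.2%/17.8% trajectory proportions — the same rule used for
#'   dropout splitting; `"to_remission"` adds it to the remission entry.
#'   If a sensitivity sweep pushes the row above 1, the LOW/HIGH
#'   return-to-LBP entries are scaled down to absorb the excess.
#'
#' Every resolution applied is recorded in the `"resolutions"` attribute
#' of the result.
#'
#' @param params An `lbp_parameters` ledger.
#' @param strategy `"DTC"` or `"TAU"`.
#' @param residual_policy Residual-mass policy for the untreated rows.
#' @param eot_residual Residual-mass policy for the end-of-treatment row.
#' @return An `lbp_transition_matrix`: a 7x7 numeric matrix with
#'   dimnames, plus attributes `strategy`, `residual_policy`,
#'   `eot_residual` and `resolutions`.
#' @examples
#' tm <- build_transition_matrix(base_parameters(), "DTC")
#' rowSums(tm)  # all exactly 1
#' @export
build_transition_matrix <- function(params, strategy,
                                    residual_policy = c("renormalize_non_treatment",
                                                        "self_loop"),
                                    eot_residual = c("trajectory_split",
                                                     "to_remission")) {
  stopifnot(inherits(params, "lbp_parameters"))
  strategy <- match.arg(strategy, lbp_strategies())
  residual_policy <- match.arg(residual_policy)
  eot_residual <- match.arg(eot_residual)

  states <- lbp_states()
  tr <- params$transitions
  m <- matrix(0, 7, 7, dimnames = list(states, states))
  resolutions <- character(0)

  check_probs <- function(p, row, allow_excess = FALSE) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("transition probability outside [0, 1] in row %s", row),
           call. = FALSE)
    }
    if (!allow_excess && sum(p) > 1 + 1e-9) {
      stop(sprintf("row %s sums to %.6f > 1: inconsistent inputs", row, sum(p)),
           call. = FALSE)
    }
  }

  # --- untreated rows -------------------------------------------------
  # the treatment-entry probability is a stated assumption swept on the
  # raw scale, so the row may come in under- or over-complete; the
  # residual policy recomposes the remaining destinations either way
  untreated <- function(row_label, other, entry) {
    check_probs(c(other, entry), row_label, allow_excess = TRUE)
    deficit <- 1 - entry - sum(other)
    if (abs(deficit) > 1e-12) {
      if (residual_policy == "renormalize_non_treatment") {
        other <- other * (1 - entry) / sum(other)
        resolutions <<- c(resolutions, sprintf(
          "%s: %.4f residual renormalized over non-treatment destinations",
          row_label, deficit))
      } else {
        if (other[row_label] + deficit < 0) {
          stop(sprintf("row %s infeasible under self_loop policy", row_label),
               call. = FALSE)
        }
        other[row_label] <- other[row_label] + deficit
        resolutions <<- c(resolutions, sprintf(
          "%s: %.4f residual added to self-loop", row_label, deficit))
      }
    }
    m[row_label, names(other)] <<- other
    m[row_label, "T_W1_4"] <<- entry
  }
  untreated("LOW", tr$low_row, tr$low_to_treatment)
  untreated("HIGH", tr$high_row, tr$high_to_treatment)

  # --- treatment tunnel rows ------------------------------------------
  rows <- tr$treatment_rows[[strategy]]
  for (spec in list(list(from = "T_W1_4", to = "T_W4_8", p = rows$w1_4),
                    list(from = "T_W4_8", to = "T_W8_12", p = rows$w4_8))) {
    p <- spec$p
    check_probs(p, spec$from)
    m[spec$from, c("LOW", "HIGH", "REMISSION")] <- p[c("LOW", "HIGH", "REMISSION")]
    m[spec$from, spec$to] <- p[["CONTINUE"]]
    deficit <- 1 - sum(p)
    if (abs(deficit) > 1e-9) {
      stop(sprintf("treatment row %s sums to %.6f, expected 1", spec$from, sum(p)),
           call. = FALSE)
    }
    m[spec$from, spec$to] <- m[spec$from, spec$to] + deficit  # absorb fp dust
  }

  # --- end-of-treatment row -------------------------------------------
  eot <- tr$end_row
  healthy <- tr$end_to_healthy[[strategy]]
  check_probs(c(eot, healthy), "T_W8_12", allow_excess = TRUE)
  deficit <- 1 - sum(eot) - healthy
  if (deficit > 1e-12) {
    if (eot_residual == "trajectory_split") {
      ls <- tr$low_trajectory_share
      eot[["LOW"]] <- eot[["LOW"]] + deficit * ls
      eot[["HIGH"]] <- eot[["HIGH"]] + deficit * (1 - ls)
      resolutions <- c(resolutions, sprintf(
        "T_W8_12: %.4f residual split to LOW/HIGH by trajectory shares", deficit))
    } else {
      eot[["REMISSION"]] <- eot[["REMISSION"]] + deficit
      resolutions <- c(resolutions, sprintf(
        "T_W8_12: %.4f residual added to REMISSION", deficit))
    }
  } else if (deficit < -1e-12) {
    lh <- eot[["LOW"]] + eot[["HIGH"]]
    if (lh + deficit < 0) {
      stop("end-of-treatment row infeasible: LOW/HIGH entries cannot absorb excess",
           call. = FALSE)
    }
    scale <- (lh + deficit) / lh
    eot[["LOW"]] <- eot[["LOW"]] * scale
    eot[["HIGH"]] <- eot[["HIGH"]] * scale
    resolutions <- c(resolutions, sprintf(
      "T_W8_12: %.4f excess absorbed by scaling LOW/HIGH", -deficit))
  }
  m["T_W8_12", names(eot)] <- eot
  m["T_W8_12", "HEALTHY"] <- healthy

  # --- remission row ---------------------------------------------------
  rem <- tr$remission_row
  check_probs(rem, "REMISSION")
  if (abs(1 - sum(rem)) > 1e-9) {
    stop(sprintf("REMISSION row sums to %.6f, expected 1", sum(rem)), call. = FALSE)
  }
  m["REMISSION", names(rem)] <- rem
  m["REMISSION", "REMISSION"] <- rem[["REMISSION"]] + (1 - sum(rem))

  # --- absorbing healthy state ----------------------------------------
  m["HEALTHY", "HEALTHY"] <- 1

  validate_transition_matrix(m)
  structure(m, class = c("lbp_transition_matrix", "matrix", "array"),
            strategy = strategy, residual_policy = residual_policy,
            eot_residual = eot_residual, resolutions = resolutions)
}

#' Validate structural invariants of a transition matrix
#'
#' Checks entries in \[0, 1\], row sums equal to 1 within 1e-12, the
#' HEALTHY unit self-loop, and the tunnel structure (T_W4_8 is entered
#' only from T_W1_4, T_W8_12 only from T_W4_8).
#'
#' @param m A 7x7 matrix with [lbp_states()] dimnames.
#' @return Invisibly `m`; errors on violation.
#' @export
validate_transition_matrix <- function(m) {
  states <- lbp_states()
  stopifnot(is.matrix(m), all(dim(m) == 7),
            identical(rownames(m), states), identical(colnames(m), states))
  if (any(m < 0) || any(m > 1)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("transition matrix rows must sum to 1 within 1e-12", call. = FALSE)
  }
  if (m["HEALTHY", "HEALTHY"] != 1) {
    stop("HEALTHY must be absorbing (unit self-loop)", call. = FALSE)
  }
  for (tun in list(c("T_W4_8", "T_W1_4"), c("T_W8_12", "T_W4_8"))) {
    feeders <- m[, tun[1]]
    if (any(feeders[setdiff(states, tun[2])] != 0)) {
      stop(sprintf("tunnel state %s may only be entered from %s",
                   tun[1], tun[2]), call. = FALSE)
    }
  }
  invisible(m)
}

#' @export
print.lbp_transition_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<lbp_transition_matrix> strategy %s (residual: %s / %s)\n",
              attr(x, "strategy"), attr(x, "residual_policy"),
              attr(x, "eot_residual")))
  print(round(unclass(x), digits))
  res <- attr(x, "resolutions")
  if (length(res)) cat(paste0("  * ", res, collapse = "\n"), "\n")
  invisible(x)
}
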