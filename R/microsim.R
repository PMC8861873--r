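#' Individual-level microsimulation through a transition matrix
#'
#' Draws `n` individual state trajectories from the same transition
#' matrix the cohort engine uses. This is an independent Monte-Carlo
#' oracle: the cohort trace is the exact expectation of these
#' trajectories, so microsimulated occupancies and value totals must
#' agree with the cohort engine within binomial/Monte-Carlo error.
#'
#' Initial states are assigned deterministically by largest-remainder
#' apportionment of `n` over the starting distribution, so the only
#' randomness is in the transitions. All randomness is controlled by
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param tm An `lbp_transition_matrix` (or 7x7 row-stochastic matrix
#'   with state dimnames).
#' @param start Starting state vector (persons; used as apportionment
#'   weights).
#' @param n Number of individuals (>= 1; `n = 0` returns an empty,
#'   flagged set).
#' @param n_cycles Number of cycles.
#' @param seed Integer seed (required).
#' @return An `lbp_trajectories` object: integer matrix `states`
#'   (n x (n_cycles + 1), values 1..7 indexing [lbp_states()]), plus
#'   `seed`, `fingerprint` (md5 of the generating matrix) and `matrix`.
#' @export
simulate_individuals <- function(tm, start, n, n_cycles, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("simulate_individuals(): an explicit seed is required", call. = FALSE)
  }
  M0 <- unclass_matrix(tm)
  # generic engine check only: any row-stochastic chain over the state
  # space is a legal generator (test fixtures need not share the LBP
  # tunnel topology)
  if (any(M0 < 0) || any(M0 > 1) || any(abs(rowSums(M0) - 1) > 1e-12)) {
    stop("simulate_individuals(): tm must be row-stochastic", call. = FALSE)
  }
  if (length(start) != 7 || any(start < 0) || sum(start) <= 0) {
    stop("simulate_individuals(): invalid start vector", call. = FALSE)
  }
  M <- M0
  empty <- n == 0
  states <- matrix(integer(0), 0, n_cycles + 1)
  if (!empty) {
    init <- apportion(start, n)
    s <- rep.int(seq_len(7), init)
    states <- matrix(NA_integer_, n, n_cycles + 1)
    states[, 1] <- s
    with_seed(seed, {
      for (t in seq_len(n_cycles)) {
        cur <- states[, t]
        nxt <- integer(n)
        for (k in seq_len(7)) {        # fixed state order => reproducible
          idx <- which(cur == k)
          if (!length(idx)) next
          if (M[k, k] == 1) {
            nxt[idx] <- k              # absorbing: no draw needed
          } else {
            nxt[idx] <- sample.int(7, length(idx), replace = TRUE, prob = M[k, ])
          }
        }
        states[, t + 1] <- nxt
      }
    })
  }
  structure(list(states = states, seed = seed,
                 fingerprint = matrix_fingerprint(M), matrix = M,
                 empty = empty),
            class = "lbp_trajectories")
}

unclass_matrix <- function(tm) {
  m <- unclass(tm)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# deterministic largest-remainder apportionment of n over weights
apportion <- function(weights, n) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

matrix_fingerprint <- function(m) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(paste(format(as.vector(m), digits = 17), collapse = ","), f)
  unname(tools::md5sum(f))
}

#' @export
print.lbp_trajectories <- function(x, ...) {
  cat(sprintf("<lbp_trajectories> %d individuals x %d cycles (seed %s)\n",
              nrow(x$states), max(ncol(x$states) - 1, 0), format(x$seed)))
  if (x$empty) cat("  [empty set]\n")
  invisible(x)
}

#' Per-state occupancy fractions of a trajectory set
#'
#' @param ts An `lbp_trajectories` object.
#' @return (n_cycles + 1) x 7 matrix of occupancy fractions, comparable
#'   with `trace$raw / cohort_size`.
#' @export
occupancy_fractions <- function(ts) {
  stopifnot(inherits(ts, "lbp_trajectories"))
  n <- nrow(ts$states)
  t(apply(ts$states, 2, tabulate, nbins = 7)) / n
}

#' Mean discounted cost and QALYs from microsimulated trajectories
#'
#' Mirrors the cohort engine's life-table correction at the individual
#' level: each cycle is valued at the mean of the values of the states
#' occupied at the cycle's start and end, discounted at the cycle's
#' start-index factor.
#'
#' @param ts An `lbp_trajectories` object.
#' @param schedule An `lbp_value_schedule`.
#' @param annual_rate Annual discount rate.
#' @return List with `mean_cost`, `mean_qalys`, standard errors
#'   (`se_cost`, `se_qalys`) and `n`.
#' @export
microsim_totals <- function(ts, schedule, annual_rate = 0.03) {
  stopifnot(inherits(ts, "lbp_trajectories"),
            inherits(schedule, "lbp_value_schedule"))
  n <- nrow(ts$states)
  if (n == 0) {
    return(list(mean_cost = NA_real_, mean_qalys = NA_real_,
                se_cost = NA_real_, se_qalys = NA_real_, n = 0L))
  }
  n_cycles <- ncol(ts$states) - 1
  cpy <- 1 / schedule$cycle_length_years
  df <- discount_factor(seq_len(n_cycles) - 1, annual_rate, cpy)
  per_person <- function(values, scale) {
    V <- matrix(values[ts$states], nrow = n)     # n x (n_cycles + 1)
    half <- (V[, seq_len(n_cycles), drop = FALSE] +
             V[, seq_len(n_cycles) + 1, drop = FALSE]) / 2
    as.vector(half %*% df) * scale
  }
  costs <- per_person(schedule$costs, 1)
  qalys <- per_person(schedule$utilities, schedule$cycle_length_years)
  list(mean_cost = mean(costs), mean_qalys = mean(qalys),
       se_cost = stats::sd(costs) / sqrt(n),
       se_qalys = stats::sd(qalys) / sqrt(n), n = n)
}

#' Randomly perturbed, structurally valid parameter sets
#'
#' Draws each swept parameter uniformly within its sensitivity bounds
#' and recomposes it through the same linkage rules the DSA uses, so
#' every returned ledger yields row-stochastic matrices for both
#' strategies by construction. Intended for property testing.
#'
#' @param base Base parameter ledger.
#' @param ranges List of `lbp_dsa_bound` objects (default
#'   [dsa_bounds()]).
#' @param n_sets Number of parameter sets to draw.
#' @param seed Integer seed.
#' @return List of `lbp_parameters` objects; each carries the draw in
#'   its `"perturbation"` attribute.
#' @export
perturb_parameters <- function(base, ranges = dsa_bounds(base), n_sets, seed) {
  stopifnot(inherits(base, "lbp_parameters"), n_sets >= 0)
  for (b in ranges) {
    if (b$low > b$high) {
      stop(sprintf("perturb_parameters(): infeasible range for %s",
                   b$parameter_id), call. = FALSE)
    }
  }
  if (n_sets == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      p <- base
      draw <- vapply(ranges, function(b) stats::runif(1, b$low, b$high),
                     numeric(1))
      names(draw) <- vapply(ranges, `[[`, "", "parameter_id")
      for (b in ranges) p <- b$apply(p, draw[[b$parameter_id]])
      attr(p, "perturbation") <- list(draw = draw, seed = seed, index = i)
      p
    })
  })
}
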