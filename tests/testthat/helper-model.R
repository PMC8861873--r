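# shared fixtures built in code

base_p <- base_parameters()

base_run <- function(strategy, horizon_years = 3, params = base_p, ...) {
  run_strategy(params, strategy, horizon_years = horizon_years, ...)
}

# identity chain over the 7 states (legal: HEALTHY self-loop, tunnels
# unreachable so their entry restriction is vacuous)
identity_tm <- function() {
  m <- diag(7)
  dimnames(m) <- list(lbp_states(), lbp_states())
  m
}

# two "useful" states: LOW splits evenly between staying and absorbing
# into HEALTHY; everything else parks in self-loops
toy_split_tm <- function(p_stay = 0.5) {
  m <- identity_tm()
  m["LOW", "LOW"] <- p_stay
  m["LOW", "HEALTHY"] <- 1 - p_stay
  m
}

# a flat schedule: one utility and one cost everywhere
flat_schedule <- function(utility, cost, cycles_per_year = 12, strategy = "DTC") {
  structure(list(
    costs = stats::setNames(rep(cost, 7), lbp_states()),
    utilities = stats::setNames(rep(utility, 7), lbp_states()),
    cycle_length_years = 1 / cycles_per_year,
    strategy = strategy
  ), class = "lbp_value_schedule")
}

expect_row_stochastic <- function(m) {
  expect_true(all(m >= 0) && all(m <= 1))
  expect_lt(max(abs(rowSums(m) - 1)), 1e-12)
}
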