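test_that("discount factors follow annual compounding per cycle", {
  expect_identical(discount_factor(0, 0.03, 12), 1)
  expect_equal(discount_factor(12, 0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(13, 0.03, 13), 1 / 1.03)
  expect_identical(discount_factor(26, 0, 13), 1)
  # strictly decreasing in cycle index for positive rates
  f <- discount_factor(0:60, 0.03, 12)
  expect_true(all(diff(f) < 0))
  expect_error(discount_factor(-1, 0.03), "non-negative")
})

test_that("cohort propagation handles degenerate chains exactly", {
  start <- c(1000, 0, 0, 0, 0, 0, 0)
  tr <- run_cohort(identity_tm(), start, 5)
  expect_equal(tr$raw, matrix(start, 6, 7, byrow = TRUE), ignore_attr = TRUE)

  tr2 <- run_cohort(toy_split_tm(0.5), start, 1)
  expect_equal(unname(tr2$raw[2, c("LOW", "HEALTHY")]), c(500, 500))
})

test_that("cohort mass is conserved over long horizons", {
  for (s in lbp_strategies()) {
    tm <- build_transition_matrix(base_p, s)
    tr <- run_cohort(tm, start_vector(base_p), 65)
    expect_lt(max(abs(rowSums(tr$raw) - 10000)), 1e-9)
    expect_true(all(tr$raw >= 0))
    expect_equal(tr$corrected, (tr$raw[1:65, ] + tr$raw[2:66, ]) / 2,
                 ignore_attr = "dimnames")
  }
})

test_that("flat-schedule accrual matches the closed form", {
  # constant occupancy, utility 0.8, 12 cycles, no discounting
  # => 0.8 QALYs per person-year
  tr <- run_cohort(identity_tm(), c(1000, 0, 0, 0, 0, 0, 0), 12)
  tot <- accrue_values(tr, flat_schedule(utility = 0.8, cost = 120), 0)
  expect_equal(tot$discounted_qalys, 0.8)
  expect_equal(tot$discounted_cost, 120 * 12)
  expect_equal(tot$discounted_cost, tot$undiscounted_cost)
})

test_that("per-state breakdowns sum to the totals", {
  for (s in lbp_strategies()) {
    tot <- base_run(s)$totals
    expect_equal(sum(tot$per_state_cost), tot$discounted_cost, tolerance = 1e-12)
    expect_equal(sum(tot$per_state_qalys), tot$discounted_qalys,
                 tolerance = 1e-12)
  }
})

test_that("life-table totals are bracketed by start- and end-of-cycle accrual", {
  tm <- build_transition_matrix(base_p, "DTC")
  tr <- run_cohort(tm, start_vector(base_p), 36)
  sched <- value_schedule(base_p, "DTC")
  n <- 36
  df <- discount_factor(0:(n - 1), 0.03, 12)
  val <- function(occ, v, scale) sum(df * (occ %*% v)) * scale / tr$cohort_size
  lt <- accrue_values(tr, sched, 0.03)
  for (spec in list(list(v = sched$costs, s = 1, got = lt$discounted_cost),
                    list(v = sched$utilities, s = sched$cycle_length_years,
                         got = lt$discounted_qalys))) {
    at_start <- val(tr$raw[1:n, ], spec$v, spec$s)
    at_end <- val(tr$raw[2:(n + 1), ], spec$v, spec$s)
    expect_gte(spec$got, min(at_start, at_end))
    expect_lte(spec$got, max(at_start, at_end))
  }
})

test_that("discounting strictly reduces positive totals", {
  for (s in lbp_strategies()) {
    tm <- build_transition_matrix(base_p, s)
    tr <- run_cohort(tm, start_vector(base_p), 36)
    sched <- value_schedule(base_p, s)
    disc <- accrue_values(tr, sched, 0.03)
    expect_lt(disc$discounted_cost, disc$undiscounted_cost)
    expect_lt(disc$discounted_qalys, disc$undiscounted_qalys)
    none <- accrue_values(tr, sched, 0)
    expect_equal(none$discounted_cost, none$undiscounted_cost)
  }
})

test_that("structural errors are raised on malformed inputs", {
  expect_error(run_cohort(identity_tm(), rep(1, 6), 5), "length 7")
  expect_error(run_cohort(identity_tm(), c(-1, rep(1, 6)), 5), "non-negative")
  expect_error(run_cohort(identity_tm(), rep(1, 7), 0), "at least 1")
  expect_error(run_cohort(matrix(1, 3, 3), rep(1, 7), 5), "7x7")
})
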