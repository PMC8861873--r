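test_that("ICER quadrant logic is classified exhaustively", {
  cases <- list(
    list(dc = 100, dq = 0.02, label = "ICER", value = 5000),
    list(dc = -100, dq = 0.02, label = "intervention_dominant", value = NA_real_),
    list(dc = 100, dq = -0.02, label = "comparator_dominant", value = NA_real_,
         strict = TRUE),
    list(dc = -100, dq = -0.02, label = "comparator_dominant", value = NA_real_,
         strict = FALSE),                              # SW: non-strict by convention
    list(dc = 0, dq = 0.02, label = "intervention_dominant", value = NA_real_),
    list(dc = 0, dq = -0.02, label = "comparator_dominant", value = NA_real_),
    list(dc = 100, dq = 0, label = "undefined_ratio", value = NA_real_),
    list(dc = -100, dq = 0, label = "undefined_ratio", value = NA_real_),
    list(dc = 0, dq = 0, label = "indeterminate", value = NA_real_)
  )
  for (cs in cases) {
    got <- icer(cs$dc, cs$dq)
    expect_identical(got$label, cs$label)
    expect_equal(got$value, cs$value)
    if (!is.null(cs$strict)) expect_identical(got$strict, cs$strict)
  }
  # value present iff the outcome is a proper ratio
  expect_false(is.na(icer(1, 1)$value))
})

test_that("incremental outcomes are antisymmetric in the strategy order", {
  dtc <- base_run("DTC")$totals
  tau <- base_run("TAU")$totals
  ab <- incremental_outcomes(dtc, tau)
  ba <- incremental_outcomes(tau, dtc)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qalys, -ba$delta_qalys)

  same <- incremental_outcomes(dtc, dtc)
  expect_equal(same$delta_cost, 0)
  expect_identical(same$dominance_label, "indeterminate")
})

test_that("incremental outcomes refuse mismatched run settings", {
  dtc2 <- base_run("DTC", horizon_years = 2)$totals
  tau3 <- base_run("TAU", horizon_years = 3)$totals
  expect_error(incremental_outcomes(dtc2, tau3), "horizon")
})

test_that("annualized values times the horizon recover the totals", {
  tot <- base_run("DTC")$totals
  a <- annualize(tot)
  expect_equal(a$cost_per_year * 3, tot$discounted_cost)
  expect_equal(a$qalys_per_year * 3, tot$discounted_qalys)
  one <- annualize(tot, 1)
  expect_equal(one$cost_per_year, tot$discounted_cost)
})

test_that("resource utilization follows its stated convention", {
  # all mass absorbed in HEALTHY: no consultations, no prescriptions
  tr <- run_cohort(identity_tm(), c(0, 0, 0, 0, 0, 0, 1000), 12)
  ru <- resource_utilization(tr, base_p)
  expect_equal(ru$consultations_per_year, 0)
  expect_equal(ru$prescriptions_total, 0)

  # relative utilization between strategies is convention-free: treatment
  # as usual generates more consultations and more prescriptions
  rd <- resource_utilization(base_run("DTC")$trace, base_p)
  rt <- resource_utilization(base_run("TAU")$trace, base_p)
  expect_gt(rt$consultations_per_year, rd$consultations_per_year)
  expect_gt(rt$prescriptions_total / rd$prescriptions_total, 1.0)
  expect_lt(rt$prescriptions_total / rd$prescriptions_total, 1.2)
  expect_match(ru$convention, "GP")
})

test_that("cost-effectiveness plane export carries points and thresholds", {
  empty <- ce_plane_points(list())
  expect_equal(nrow(empty$points), 0)

  scen <- scenario_suite(base_p)
  plane <- ce_plane_points(scen$results)
  expect_equal(nrow(plane$points), 7)
  expect_equal(plane$thresholds$threshold, c(10000, 20000))
  base_pt <- plane$points[plane$points$scenario_id == "base", ]
  # base case lies below the 10,000 EUR/QALY threshold line
  expect_lt(base_pt$delta_cost, 10000 * base_pt$delta_qalys)
})
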