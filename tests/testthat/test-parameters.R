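test_that("parameter ledger carries the published inputs", {
  expect_equal(base_p$utilities$DTC[["T_W8_12"]], 0.748)
  expect_equal(base_p$utilities$TAU[["T_W8_12"]], 0.729)
  expect_equal(base_p$state_costs$DTC[["HIGH"]], 588.96)
  expect_equal(unname(base_p$settings$start),
               c(5320, 1120, 3560))
  expect_equal(sum(base_p$settings$start), base_p$settings$cohort_size)
  expect_equal(base_p$transitions$low_trajectory_share +
                 (1 - base_p$transitions$low_trajectory_share), 1)
})

test_that("derived unit costs reproduce published values to the cent", {
  # physiotherapy block: sessions x price x (1 + copay) + prescription charge
  expect_identical(physiotherapy_cycle_cost(6, 21.11, 10, 0.10), 149.33)
  expect_identical(physiotherapy_cycle_cost(4, 21.11, 10, 0.10), 102.88)
  expect_identical(physiotherapy_cycle_cost(12, 21.11, 10, 0.10), 288.65)
  expect_identical(physiotherapy_cycle_cost(1, 21.11, 0, 0), 21.11)

  expect_identical(daily_wage(3092, 21), 147.24)
  expect_identical(daily_wage(2100, 21), 100)
  expect_identical(daily_wage(0, 21), 0)
  # sensitivity bounds are +/- 10% of the daily wage, rounded to cents
  expect_equal(round(147.24 * 0.9, 2), 132.52)
  expect_equal(round(147.24 * 1.1, 2), 161.96)

  # first-treatment-month decomposition: app + GP + specialist +
  # pharmacotherapy + diagnostics + one day of absenteeism
  uc <- base_p$unit_costs
  expect_equal(
    round(uc$app_price + uc$gp_consultation + uc$specialist_consultation +
            uc$pharmacotherapy + uc$diagnostics + daily_wage(), 2),
    base_p$state_costs$DTC[["T_W1_4"]])
})

test_that("treatment-entry recomposition reproduces the published DSA costs", {
  expect_identical(treatment_entry_cost("DTC", 99.96, base_p), 335.08)
  expect_identical(treatment_entry_cost("DTC", 299.96, base_p), 535.08)
  expect_identical(treatment_entry_cost("TAU", 102.88, base_p), 331.40)
  expect_identical(treatment_entry_cost("TAU", 288.65, base_p), 517.17)
  # identity: base program component returns the base state cost
  expect_identical(treatment_entry_cost("DTC", 239.96, base_p), 475.08)
  expect_identical(treatment_entry_cost("TAU", 149.33, base_p), 377.85)
})

test_that("dropout_split matches the published tunnel rows at 4 decimals", {
  cases <- list(
    list(a = 0.125, row = c(0.875, 0.0625, 0.0514, 0.0111)),  # app, both months
    list(a = 0.065, row = c(0.935, 0.0325, 0.0267, 0.0058)),  # TAU month one
    list(a = 0.043, row = c(0.957, 0.0215, 0.0177, 0.0038))   # TAU month two
  )
  for (cs in cases) {
    s <- dropout_split(cs$a, 0.5, 0.822)
    expect_equal(round(c(s$continue, s$to_remission, s$to_low, s$to_high), 4),
                 cs$row)
  }
  s0 <- dropout_split(0, 0.5, 0.822)
  expect_equal(unlist(s0), c(continue = 1, to_remission = 0, to_low = 0,
                             to_high = 0))
})

test_that("dropout_split components always sum to one", {
  grid <- expand.grid(a = seq(0, 1, by = 0.2),
                      r = seq(0, 1, by = 0.25),
                      ls = seq(0, 1, by = 0.25))
  for (i in seq_len(nrow(grid))) {
    s <- dropout_split(grid$a[i], grid$r[i], grid$ls[i])
    expect_lt(abs(sum(unlist(s)) - 1), 1e-12)
    expect_true(all(unlist(s) >= 0))
  }
})

test_that("domain errors are raised on invalid composition inputs", {
  expect_error(dropout_split(1.2), "\\[0, 1\\]")
  expect_error(dropout_split(-0.1), "\\[0, 1\\]")
  expect_error(physiotherapy_cycle_cost(0), "at least one session")
  expect_error(daily_wage(3092, 0), "at least 1")
  expect_error(treatment_entry_cost("DTC", -5), "non-negative")
})

test_that("set_attrition recomposes only the targeted strategy's rows", {
  p <- set_attrition(base_p, "DTC", c(0.30, 0.30))
  r1 <- p$transitions$treatment_rows$DTC$w1_4
  expect_equal(unname(r1[["CONTINUE"]]), 0.70)
  expect_equal(unname(r1[["REMISSION"]]), 0.15)
  expect_equal(unname(r1[["LOW"]]), 0.30 * 0.5 * 0.822)
  expect_identical(p$transitions$treatment_rows$TAU,
                   base_p$transitions$treatment_rows$TAU)
  expect_equal(p$transitions$attrition$DTC, c(0.30, 0.30))
})
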