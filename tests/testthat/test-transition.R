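test_that("published rows appear verbatim in the constructed matrices", {
  dtc <- build_transition_matrix(base_p, "DTC")
  tau <- build_transition_matrix(base_p, "TAU")

  expect_equal(unname(dtc["T_W1_4", c("LOW", "HIGH", "T_W4_8", "REMISSION")]),
               c(0.0514, 0.0111, 0.875, 0.0625))
  expect_equal(unname(tau["T_W1_4", c("LOW", "HIGH", "T_W4_8", "REMISSION")]),
               c(0.0267, 0.0058, 0.935, 0.0325))
  expect_equal(unname(tau["T_W4_8", c("LOW", "HIGH", "T_W8_12", "REMISSION")]),
               c(0.0177, 0.0038, 0.957, 0.0215))
  expect_equal(unname(dtc["T_W8_12", c("LOW", "HIGH", "REMISSION", "HEALTHY")]),
               c(0.235, 0.051, 0.614, 0.10))
  expect_equal(unname(dtc["REMISSION", c("LOW", "HIGH", "REMISSION")]),
               c(0.505, 0.109, 0.386))
  # treatment-entry assumptions stay fixed under the default policy
  expect_equal(unname(dtc["LOW", "T_W1_4"]), 0.75)
  expect_equal(unname(dtc["HIGH", "T_W1_4"]), 0.80)
  # HEALTHY is the absorbing state
  expect_equal(unname(dtc["HEALTHY", ]), c(0, 0, 0, 0, 0, 0, 1))
})

test_that("residual row mass is resolved per policy and recorded", {
  renorm <- build_transition_matrix(base_p, "DTC",
                                    residual_policy = "renormalize_non_treatment")
  # LOW row deficit 0.05 spread proportionally over 0.16/0.01/0.03
  expect_equal(unname(renorm["LOW", c("LOW", "HIGH", "REMISSION")]),
               c(0.16, 0.01, 0.03) * 0.25 / 0.20)
  self <- build_transition_matrix(base_p, "DTC", residual_policy = "self_loop")
  expect_equal(unname(self["LOW", "LOW"]), 0.16 + 0.05)
  expect_equal(unname(self["HIGH", "HIGH"]), 0.08 + 0.10)
  expect_row_stochastic(renorm)
  expect_row_stochastic(self)
  expect_true(length(attr(renorm, "resolutions")) >= 2)
})

test_that("TAU end-of-treatment deficit is split over the return trajectories", {
  tau <- build_transition_matrix(base_p, "TAU")
  # 0.05 deficit split 82.2% / 17.8% onto LOW / HIGH
  expect_equal(unname(tau["T_W8_12", "LOW"]), 0.235 + 0.05 * 0.822)
  expect_equal(unname(tau["T_W8_12", "HIGH"]), 0.051 + 0.05 * 0.178)
  expect_equal(unname(tau["T_W8_12", "HEALTHY"]), 0.05)
  expect_row_stochastic(tau)

  alt <- build_transition_matrix(base_p, "TAU", eot_residual = "to_remission")
  expect_equal(unname(alt["T_W8_12", "REMISSION"]), 0.614 + 0.05)
  expect_row_stochastic(alt)
})

test_that("tunnel states are entered only from their predecessor", {
  for (s in lbp_strategies()) {
    m <- build_transition_matrix(base_p, s)
    others <- setdiff(lbp_states(), "T_W1_4")
    expect_true(all(m[others, "T_W4_8"][setdiff(others, "T_W1_4")] == 0))
    expect_true(all(m[setdiff(lbp_states(), "T_W4_8"), "T_W8_12"] == 0))
    expect_error(validate_transition_matrix(m), NA)
  }
})

test_that("invalid probability inputs raise structured errors", {
  bad <- base_p
  bad$transitions$remission_row[["LOW"]] <- 1.2
  expect_error(build_transition_matrix(bad, "DTC"), "outside \\[0, 1\\]")

  over <- base_p
  over$transitions$remission_row <- c(LOW = 0.6, HIGH = 0.3, REMISSION = 0.2)
  expect_error(build_transition_matrix(over, "DTC"), "inconsistent|expected 1")
})

test_that("all matrices from perturbed parameter sets are row-stochastic", {
  sets <- perturb_parameters(base_p, dsa_bounds(base_p), n_sets = 25, seed = 42)
  for (p in sets) {
    for (s in lbp_strategies()) {
      for (pol in c("renormalize_non_treatment", "self_loop")) {
        m <- build_transition_matrix(p, s, residual_policy = pol)
        expect_row_stochastic(m)
      }
    }
  }
})
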