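test_that("a non-growing culture never dilutes and oxygen saturates", {
  kin <- kinetic_params(mu_max = 1e-9, K_I_S = 114.5, K_I_i = 72.46)
  sim <- simulate_culture(c(100, 300), kin, hold_hours = 6)
  expect_true(all(sim$results$dilutions == 0))
  expect_equal(sim$results$X_gL, rep(0.1, 2), tolerance = 1e-4)
  expect_equal(sim$results$dO2, rep(100, 2), tolerance = 1e-3)
})

test_that("reported growth rate matches the Haldane rate at the effective light", {
  kin <- kinetic_params_case(1)
  sim <- simulate_culture(c(100, 300, 950), kin, hold_hours = 24)
  ok <- !is.na(sim$results$mu_obs_h)
  expect_true(all(ok))
  expect_equal(sim$results$mu_obs_h[ok],
               growth_rate(sim$results$I_eff_Wm2[ok], kin),
               tolerance = 0.02)
})

test_that("the staircase shows limitation, saturation and inhibition", {
  sim <- simulate_culture(c(50, 100, 200, 300, 500, 950, 1200),
                          kinetic_params_case(2), calibration_case = 2)
  mu <- sim$results$mu_obs_h
  peak <- which.max(mu)
  expect_gt(peak, 1)
  expect_lt(peak, length(mu))
  expect_true(all(diff(mu[1:peak]) > 0))
  expect_true(all(diff(mu[peak:length(mu)]) < 0))
})

test_that("the turbidostat confines OD730 to its band", {
  sim <- simulate_culture(c(300, 500), kinetic_params_case(1),
                          hold_hours = 12)
  s <- sim$series
  after_first <- s[cumsum(s$diluted) > 0, ]
  expect_gt(nrow(after_first), 10)
  expect_true(all(after_first$OD730 >= 0.39 - 1e-9))
  expect_true(all(after_first$OD730 <= 0.41 + 1e-9))
})

test_that("the coupled loop reaches a stable growth rate within a hold", {
  sim <- simulate_culture(300, kinetic_params_case(1), hold_hours = 24)
  s <- sim$series
  late <- s$mu_model[s$time > 18]
  expect_lt(max(late) - min(late), 1e-3)
})

test_that("invalid configurations are rejected before running", {
  kin <- kinetic_params_case(1)
  expect_error(simulate_culture(300, kin,
                                geom = reactor_geometry(fill_height = 0)),
               "fill_height")
  expect_error(simulate_culture(300, kin, dt_h = 0), "dt_h")
})

test_that("simulations are deterministic", {
  kin <- kinetic_params_case(3)
  a <- simulate_culture(c(100, 500), kin, hold_hours = 4)
  b <- simulate_culture(c(100, 500), kin, hold_hours = 4)
  expect_identical(a$results, b$results)
})

test_that("dom and two-flux light modes agree on the effective irradiance", {
  kin <- kinetic_params_case(1)
  fast <- simulate_culture(300, kin, hold_hours = 1, dt_h = 0.25)
  dom <- simulate_culture(300, kin, hold_hours = 1, dt_h = 0.25,
                          light_mode = "dom", dom_spacing = 0.004)
  # the 3-D field sees probe shadows and the headspace, so allow a wider
  # band than the 1-D comparison
  expect_equal(dom$results$I_eff_Wm2, fast$results$I_eff_Wm2,
               tolerance = 0.15)
})
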