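test_that("photon accounting follows the inlet-outlet difference", {
  expect_equal(photons_available(300, 300, 0.01, 3600), 0)
  # 100 uE net over the light-facing liquid cross-section for 24 h
  area <- 0.11 * 0.1439
  expect_equal(photons_available(300, 200, area, 86400), 0.1368,
               tolerance = 1e-3)
  expect_equal(photons_available(300, 200, area, 2 * 86400),
               2 * photons_available(300, 200, area, 86400))
  expect_error(photons_available(100, 200, 0.01, 10), "I_in >= I_out")
})

test_that("biomass production matches its closed forms", {
  expect_equal(biomass_produced(0, 0.1, 0.38, 24), 0)
  expect_equal(biomass_produced(0.05, 0.1, 0.38, 24),
               0.038 * (exp(1.2) - 1), tolerance = 1e-12)
  expect_equal(biomass_produced(0.05, 0.1, 0.38, 24), 0.0882,
               tolerance = 1e-3)
  # first-order agreement in the small-rate limit
  mu <- 0.005
  expect_equal(biomass_produced(mu, 0.1, 0.38, 24),
               mu * 0.1 * 0.38 * 24, tolerance = 0.01)
  expect_equal(biomass_produced(0.05, 0.1, 0.38, 24, method = "continuous"),
               0.05 * 0.1 * 0.38 * 24, tolerance = 1e-12)
})

test_that("efficiency is the biomass-to-photon ratio with guarded edge cases", {
  expect_equal(photosynthetic_efficiency(0, 1.2), 0)
  expect_equal(photosynthetic_efficiency(0.5, 1.2), 0.4167, tolerance = 1e-3)
  expect_error(photosynthetic_efficiency(0.5, 0), "undefined")
})

test_that("staircase efficiency decreases with setpoint and favours the liquid phase", {
  for (cs in c(1, 2)) {
    sim <- simulate_culture(c(50, 100, 200, 300, 500, 950, 1200),
                            kinetic_params_case(cs), calibration_case = cs)
    eff <- efficiency_table(sim)
    wide <- tidyr::pivot_wider(eff[c("setpoint_uE", "variant",
                                     "efficiency_g_mol")],
                               names_from = "variant",
                               values_from = "efficiency_g_mol")
    expect_true(all(diff(wide$whole_reactor) <= 0))
    expect_true(all(diff(wide$liquid_phase) <= 0))
    # fewer losses are counted in the liquid-phase variant
    expect_true(all(wide$liquid_phase >= wide$whole_reactor))
    expect_true(all(eff$efficiency_g_mol >= 0))
  }
})

test_that("calibration changes the efficiency ordering between light extremes", {
  # each calibration case carries both its source model and the kinetic
  # constants apparent under that calibration
  e_case <- function(cs) {
    sim <- simulate_culture(c(50, 1200), kinetic_params_case(cs),
                            calibration_case = cs)
    eff <- efficiency_table(sim)
    eff$efficiency_g_mol[eff$variant == "whole_reactor"]
  }
  e1 <- e_case(1); e2 <- e_case(2)
  expect_lt(e1[1], e2[1]) # low light: attenuated case-1 panel grows slower
  expect_gt(e1[2], e2[2]) # high light: case 1 escapes photo-inhibition
})
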