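test_that("noiseless staircase data give exact Haldane recovery", {
  for (cs in 1:3) {
    kin <- kinetic_params_case(cs)
    I <- microE_to_wm2(staircase_uE)
    fit <- fit_haldane(data.frame(I_Wm2 = I, mu_h = growth_rate(I, kin)))
    est <- tidy(fit)$estimate
    expect_equal(est, c(kin$mu_max, kin$K_I_S, kin$K_I_i),
                 tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the fitter accepts uE inputs and enforces its preconditions", {
  kin <- kinetic_params_case(1)
  d <- data.frame(I_uE = staircase_uE,
                  mu_h = growth_rate(microE_to_wm2(staircase_uE), kin))
  expect_equal(tidy(fit_haldane(d))$estimate[1], kin$mu_max,
               tolerance = 1e-6)
  expect_error(fit_haldane(data.frame(I_Wm2 = c(1, 2, 3),
                                      mu_h = c(0.1, 0.2, 0.25))),
               "4 distinct")
})

test_that("saturation-only (Monod) data push the inhibition constant to its bound", {
  I <- microE_to_wm2(staircase_uE)
  d <- data.frame(I_Wm2 = I, mu_h = 0.3 * I / (50 + I))
  expect_warning(fit_haldane(d), "monotone")
  fit <- suppressWarnings(fit_haldane(d))
  expect_true("K_I_i_at_bound" %in% fit$flags)
  expect_gt(tidy(fit)$estimate[3], 1e4)
})

test_that("median estimates stay within 10% under 2% noise", {
  kin <- kinetic_params_case(2)
  ests <- sapply(1:10, function(s) {
    tidy(fit_haldane(make_recovery_data(kin, 0.02, 3, seed = 100 + s),
                     seed = s))$estimate
  })
  meds <- apply(ests, 1, median)
  truth <- c(kin$mu_max, kin$K_I_S, kin$K_I_i)
  expect_true(all(abs(meds / truth - 1) < 0.10))
})

test_that("multi-start fitting is deterministic for a fixed seed", {
  d <- make_recovery_data(kinetic_params_case(1), 0.05, 2, seed = 4)
  f1 <- fit_haldane(d, seed = 42)
  f2 <- fit_haldane(d, seed = 42)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("absorption-law fitting inverts its forward model exactly", {
  ab <- absorption_law_defaults()
  X <- c(0.1, 0.5, 1, 2)
  Tf <- exp(-biomass_absorption_coefficient(X) * 0.024)
  fit <- fit_absorption_law(data.frame(X_gL = X, T_frac = Tf), L = 0.024)
  expect_equal(tidy(fit)$estimate, unname(ab), tolerance = 1e-10)
  # abiotic losses removed multiplicatively before the log transform
  fit2 <- fit_absorption_law(data.frame(X_gL = X, T_frac = 0.9 * Tf),
                             L = 0.024, abiotic_transmission = 0.9)
  expect_equal(tidy(fit2)$estimate, unname(ab), tolerance = 1e-10)
  # fitted curve strictly increasing whenever a, b > 0
  k <- tidy(fit)$estimate
  expect_true(all(diff(k[1] * X^k[2]) > 0))
})

test_that("degenerate absorption designs are rejected", {
  expect_error(fit_absorption_law(data.frame(X_gL = c(1, 1, 1),
                                             T_frac = c(0.9, 0.9, 0.9))),
               "unidentifiable|distinct")
  expect_error(fit_absorption_law(data.frame(X_gL = c(0.1, 1, 2),
                                             T_frac = c(1.2, 0.5, 0.4))),
               "0, 1")
})

test_that("calibration factors are recovered from abiotic outlet data", {
  geom <- reactor_geometry()
  optics <- optical_properties()
  model1 <- function(s, cs) {
    vapply(s, function(si) {
      panel_light_1d(geom, optics,
                     light_source(si, cs, calibration_factor = 1))$I_out_uE
    }, numeric(1))
  }
  truth <- c(`1` = 1.0, `2` = 1.25, `3` = 1.25)
  sp <- c(50, 200, 500, 1200)
  set.seed(21)
  dat <- purrr::map_dfr(1:3, function(cs) {
    tibble::tibble(setpoint_uE = sp, case = cs,
                   I_out_uE = truth[[cs]] * model1(sp, cs) *
                     exp(rnorm(length(sp), 0, 0.01)))
  })
  fit <- fit_calibration_factors(dat)
  expect_equal(tidy(fit)$estimate, unname(truth), tolerance = 0.03)
  expect_lt(tidy(fit)$estimate[1], tidy(fit)$estimate[2])

  # noiseless identity data recover exactly 1
  ident <- purrr::map_dfr(1:3, function(cs) {
    tibble::tibble(setpoint_uE = sp, case = cs, I_out_uE = model1(sp, cs))
  })
  expect_equal(tidy(fit_calibration_factors(ident))$estimate, rep(1, 3),
               tolerance = 1e-10)
})

test_that("partial calibration data warn and single setpoints error", {
  one_case <- tibble::tibble(setpoint_uE = c(100, 300), case = 2,
                             I_out_uE = c(50, 150))
  expect_warning(fit_calibration_factors(one_case), "one calibration case")
  expect_error(suppressWarnings(
    fit_calibration_factors(tibble::tibble(setpoint_uE = 100, case = 2,
                                           I_out_uE = 50))),
    ">= 2 setpoints")
})
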