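fluid <- fluid_properties()
cell <- cell_properties()

test_that("drag rate follows Stokes' law", {
  expect_equal(drag_rate(fluid, cell), 18e-3 / (1050 * (2e-6)^2),
               tolerance = 1e-12)
  expect_equal(drag_rate(fluid, cell), 4.2857e6, tolerance = 1e-4)
  big <- cell_properties(particle_diameter = 4e-6)
  expect_equal(drag_rate(fluid, big), drag_rate(fluid, cell) / 4,
               tolerance = 1e-12)
  expect_identical(drag_rate(fluid_properties(dynamic_viscosity = 0), cell),
                   0)
})

test_that("drag force is proportional to slip and vanishes without it", {
  p <- tibble::tibble(mass = 1e-15, vx = 0.001, vy = 0, vz = 0)
  vf <- tibble::tibble(vx = 0.001, vy = 0, vz = 0)
  expect_true(all(drag_force(p, vf, 4.2857e6) == 0))
  vf2 <- tibble::tibble(vx = 0.002, vy = 0, vz = 0)
  f <- drag_force(p, vf2, 4.2857e6)
  expect_equal(f$fx, 1e-15 * 4.2857e6 * 1e-3, tolerance = 1e-10)
  expect_gt(f$fx, 0) # toward the fluid velocity
})

test_that("gravity force respects buoyancy", {
  p <- tibble::tibble(mass = 1e-15)
  neutral <- cell_properties(particle_density = 1000)
  expect_true(all(gravity_force(p, fluid, neutral) == 0))
  f <- gravity_force(p, fluid, cell)
  expect_equal(f$fz / 1e-15, -9.81 * 50 / 1050, tolerance = 1e-12)
  light <- cell_properties(particle_density = 900)
  expect_gt(gravity_force(p, fluid, light)$fz, 0)
})

test_that("elastic pair forces have the Hookean sign and magnitude", {
  ip <- interaction_params(k_EL = 2e-9, r_0 = 1e-5, cutoff = 4e-5)
  # at the equilibrium distance both forces vanish
  pos <- tibble::tibble(x = c(0, 1e-5), y = c(0, 0), z = c(0, 0))
  expect_equal(max(abs(as.matrix(elastic_forces(pos, ip)))), 0,
               tolerance = 1e-20)
  # beyond it: mutual attraction of magnitude k (r - r0) along the line
  pos2 <- tibble::tibble(x = c(0, 3e-5), y = c(0, 0), z = c(0, 0))
  f <- elastic_forces(pos2, ip)
  expect_equal(f$fx[1], 2e-9 * 2e-5, tolerance = 1e-12)
  expect_equal(f$fx[2], -2e-9 * 2e-5, tolerance = 1e-12)
  expect_equal(f$fy, c(0, 0))
})

test_that("cell-list forces equal the brute-force oracle with zero net force", {
  ip <- interaction_params(k_EL = 5e-9, r_0 = 8e-6, cutoff = 3.2e-5)
  for (s in 1:5) {
    set.seed(s)
    n <- sample(2:10, 1)
    pos <- tibble::tibble(x = runif(n, 0, 1e-4), y = runif(n, 0, 1e-4),
                          z = runif(n, 0, 1e-4))
    f <- as.matrix(elastic_forces(pos, ip))
    ref <- brute_elastic(pos, ip$k_EL, ip$r_0, ip$cutoff)
    expect_equal(f, ref, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(colSums(f)), c(0, 0, 0), tolerance = 1e-22)
  }
  # denser configuration exercising multiple cells
  set.seed(99)
  pos <- tibble::tibble(x = runif(200, 0, 2e-4), y = runif(200, 0, 2e-4),
                        z = runif(200, 0, 2e-4))
  f <- as.matrix(elastic_forces(pos, ip))
  ref <- brute_elastic(pos, ip$k_EL, ip$r_0, ip$cutoff)
  expect_equal(f, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("coincident particles get a finite deterministic kick", {
  ip <- interaction_params(k_EL = 1e-9, r_0 = 1e-5, cutoff = 4e-5)
  pos <- tibble::tibble(x = c(1e-5, 1e-5), y = c(0, 0), z = c(0, 0))
  f <- elastic_forces(pos, ip)
  expect_true(all(is.finite(as.matrix(f))))
  expect_equal(abs(f$fx), rep(1e-9 * 1e-5, 2), tolerance = 1e-20)
  expect_equal(sum(f$fx), 0, tolerance = 1e-22)
})

test_that("inertial integrator reproduces terminal settling velocity", {
  geom <- reactor_geometry()
  still <- flow_field(loop_speed = 0, stirrer_angular_speed = 0)
  Fd <- drag_rate(fluid, cell)
  v_term <- fluid$gravity * (cell$particle_density - fluid$fluid_density) /
    (cell$particle_density * Fd)
  expect_equal(v_term, 1.09e-7, tolerance = 1e-3)
  p <- tibble::tibble(id = 1, x = 0.05, y = 0.012, z = 0.1,
                      vx = 0, vy = 0, vz = 0,
                      mass = cell$initial_particle_mass)
  dt <- 0.1 / Fd
  for (i in 1:50) { # 5 relaxation times
    p <- step_ensemble(p, still, fluid, cell, dt, geom, mode = "inertial")
  }
  expect_equal(-p$vz, v_term, tolerance = 0.01)
})

test_that("velocity relaxes exponentially at the drag rate", {
  geom <- reactor_geometry()
  nograv <- fluid_properties(gravity = 0)
  flow <- flow_field(loop_speed = 0.01, stirrer_angular_speed = 0)
  p0 <- tibble::tibble(id = 1, x = 0.055, y = 0.012, z = 0.07,
                       vx = 0, vy = 0, vz = 0,
                       mass = cell$initial_particle_mass)
  vf <- velocity_at(flow, geom, p0[, c("x", "y", "z")])
  Fd <- drag_rate(nograv, cell)
  dt <- 0.005 / Fd
  n <- 200 # total time: one relaxation time
  p <- p0
  for (i in seq_len(n)) {
    p <- step_ensemble(p, flow, nograv, cell, dt, geom, mode = "inertial")
  }
  # semi-implicit decay factor (1+Fd dt)^-n approximates exp(-Fd t) to 1%
  slip0 <- abs(vf$vx - p0$vx)
  expect_equal(abs(vf$vx - p$vx) / slip0, exp(-Fd * n * dt),
               tolerance = 0.01)
})

test_that("a force-free resting particle stays put", {
  geom <- reactor_geometry()
  still <- flow_field(loop_speed = 0, stirrer_angular_speed = 0)
  neutral <- cell_properties(particle_density = 1000)
  p <- tibble::tibble(id = 1, x = 0.03, y = 0.01, z = 0.05,
                      vx = 0, vy = 0, vz = 0, mass = 1e-15)
  p2 <- step_ensemble(p, still, fluid, neutral, 0.1, geom, mode = "inertial")
  expect_equal(p2[c("x", "y", "z")], p[c("x", "y", "z")], tolerance = 1e-15)
})

test_that("reflection keeps the ensemble inside the liquid box", {
  geom <- reactor_geometry()
  flow <- flow_field()
  p <- seed_particles(300, geom, cell, seed = 11)
  for (i in 1:400) {
    p <- step_ensemble(p, flow, fluid, cell, dt = 0.25, geom = geom)
  }
  expect_true(all(p$x >= 0 & p$x <= geom$width))
  expect_true(all(p$y >= 0 & p$y <= geom$thickness))
  expect_true(all(p$z >= 0 & p$z <= geom$fill_height))
})

test_that("light history in a uniform field is flat and scales by absorptance", {
  traj <- tibble::tibble(time = rep(0:9, each = 3), id = rep(1:3, 10),
                         x = 0.05, y = 0.01, z = 0.05)
  h <- sample_light_history(traj, 40, cell)
  expect_true(all(h$I_p == 40))
  expect_equal(h$I_ab / h$I_p, rep(cell$cell_absorptance, nrow(h)))
  st <- light_history_stats(h, kinetic_params_case(1))
  expect_equal(st$fluctuation_pct, 0)
  expect_equal(st$frac_limitation, 1) # 40 W/m2 < K_I_S = 114.5
  zero_abs <- cell_properties(cell_absorptance = 0)
  expect_true(all(sample_light_history(traj, 40, zero_abs)$I_ab == 0))
})

test_that("two-level light history splits residence time across zones", {
  kin <- kinetic_params(mu_max = 0.3, K_I_S = 100, K_I_i = 100)
  # levels I and 3I straddling the optimum at 100 W/m2
  traj <- tibble::tibble(time = rep(1:10, each = 1), id = 1,
                         x = 0, y = 0, z = 0)
  h <- tibble::tibble(time = 1:10, id = 1,
                      I_p = rep(c(60, 180), 5), I_ab = 0.5 * rep(c(60, 180), 5))
  class(h) <- c("pbr_light_history", class(h))
  st <- light_history_stats(h, kin)
  expect_equal(st$mean_Ip, 120)
  expect_equal(st$frac_limitation, 0.5) # 60 < K_I_S
  expect_equal(st$frac_inhibition, 0.5) # 180 > sqrt(100*100)
  expect_equal(st$mean_Iab / st$mean_Ip, 0.5)
  expect_error(light_history_stats(h[0, ], kin), "non-empty")
})

test_that("ensemble-mean perceived light is stationary and below the incident", {
  geom <- reactor_geometry()
  lf <- solve_dom_grid(geom, with_biomass(optical_properties(), 0.5),
                       light_source(300, 1), spacing = 0.004)
  p <- seed_particles(200, geom, cell, seed = 5)
  traj <- trace_particles(p, flow_field(), fluid, cell, dt = 0.5,
                          duration = 300, geom = geom, record_every = 5L)
  h <- sample_light_history(traj, lf, cell)
  ens <- dplyr::summarise(dplyr::group_by(h, time), m = mean(I_p),
                          .groups = "drop")
  expect_lt(mean(ens$m), emitted_intensity(light_source(300, 1)))
  # drift of the ensemble mean over the second half below 1%
  half <- ens[ens$time > max(ens$time) / 2, ]
  drift <- abs(mean(tail(half$m, 5)) - mean(head(half$m, 5))) / mean(half$m)
  expect_lt(drift, 0.01)
})
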