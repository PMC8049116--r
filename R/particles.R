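# Lagrangian particle (cell) tracking: drag, gravity/buoyancy and pairwise
# linear-elastic interactions, with specular wall reflection. Because the
# drag relaxation time of a micron-sized cell is ~0.2 us, the default
# "tracer" mode advects particles with the fluid plus the settling
# correction; the full semi-implicit inertial integrator is retained and is
# the reference surface for the force model.

#' Particle-particle interaction parameters
#'
#' @param k_EL Linear spring constant (N m^-1); 0 disables interactions.
#' @param r_0 Equilibrium inter-particle distance (m).
#' @param cutoff Interaction cutoff radius (m), at least `r_0`.
#' @return An object of class `pbr_interaction`.
#' @export
interaction_params <- function(k_EL = 0, r_0 = 1e-5, cutoff = 4e-5) {
  if (k_EL < 0) abort("`k_EL` must be >= 0.")
  if (r_0 <= 0) abort("`r_0` must be > 0.")
  if (cutoff < r_0) abort("`cutoff` must be >= `r_0`.")
  structure(list(k_EL = k_EL, r_0 = r_0, cutoff = cutoff),
            class = "pbr_interaction")
}

#' Drag rate (drag force per unit mass per unit slip)
#'
#' Stokes drag rate `F_d = 18 eta / (rho_p d_p^2)` (s^-1).
#'
#' @param fluid A [fluid_properties()].
#' @param cell A [cell_properties()].
#' @return Drag rate in s^-1.
#' @export
drag_rate <- function(fluid, cell) {
  stopifnot(inherits(fluid, "pbr_fluid"), inherits(cell, "pbr_cell"))
  if (cell$particle_diameter <= 0) abort("Particle diameter must be > 0.")
  18 * fluid$dynamic_viscosity /
    (cell$particle_density * cell$particle_diameter^2)
}

#' Drag force on particles
#'
#' `F_D = m_p F_d (v - v_p)`: proportional to the slip between the fluid
#' velocity and the particle velocity.
#'
#' @param particles Tibble with columns `mass`, `vx`, `vy`, `vz`.
#' @param fluid_velocity Tibble with columns `vx`, `vy`, `vz` (recycled if
#'   one row) giving the fluid velocity at each particle.
#' @param F_d Drag rate (s^-1) from [drag_rate()].
#' @return Tibble with force components `fx`, `fy`, `fz` (N).
#' @export
drag_force <- function(particles, fluid_velocity, F_d) {
  tibble::tibble(
    fx = particles$mass * F_d * (fluid_velocity$vx - particles$vx),
    fy = particles$mass * F_d * (fluid_velocity$vy - particles$vy),
    fz = particles$mass * F_d * (fluid_velocity$vz - particles$vz)
  )
}

#' Gravity/buoyancy force on particles
#'
#' `F_g = m_p g (rho_p - rho) / rho_p` directed along -z; vanishes at
#' neutral buoyancy and points upward for particles lighter than the fluid.
#'
#' @param particles Tibble with a `mass` column.
#' @param fluid A [fluid_properties()].
#' @param cell A [cell_properties()].
#' @return Tibble with `fx`, `fy`, `fz` (N).
#' @export
gravity_force <- function(particles, fluid, cell) {
  stopifnot(inherits(fluid, "pbr_fluid"), inherits(cell, "pbr_cell"))
  a <- -fluid$gravity *
    (cell$particle_density - fluid$fluid_density) / cell$particle_density
  tibble::tibble(fx = 0 * particles$mass, fy = 0 * particles$mass,
                 fz = particles$mass * a)
}

#' Pairwise linear-elastic forces
#'
#' For every particle pair within the cutoff,
#' `F_i = -k_EL (|r_i - r_j| - r_0) (r_i - r_j)/|r_i - r_j|` summed over
#' neighbours: attractive beyond the equilibrium distance, repulsive below
#' it, with exact action-reaction. Neighbour search uses a uniform cell
#' list keyed on the cutoff. Coincident particles are skipped and given a
#' deterministic repulsive kick of magnitude `k_EL * r_0` along +/- x.
#'
#' @param positions Tibble with columns `x`, `y`, `z` (m).
#' @param params An [interaction_params()].
#' @return Tibble with `fx`, `fy`, `fz` (N), one row per particle.
#' @export
elastic_forces <- function(positions, params) {
  stopifnot(inherits(params, "pbr_interaction"))
  n <- nrow(positions)
  if (n < 1) abort("Need at least one particle.")
  out <- matrix(0, n, 3)
  if (params$k_EL == 0 || n == 1) {
    return(tibble::tibble(fx = out[, 1], fy = out[, 2], fz = out[, 3]))
  }
  pos <- cbind(positions$x, positions$y, positions$z)
  rc <- params$cutoff
  cellidx <- floor(pos / rc)
  key <- paste(cellidx[, 1], cellidx[, 2], cellidx[, 3])
  cells <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  pairs_i <- integer(0); pairs_j <- integer(0)
  for (ck in names(cells)) {
    ids <- cells[[ck]]
    base <- as.numeric(strsplit(ck, " ", fixed = TRUE)[[1]])
    for (r in seq_len(nrow(offsets))) {
      nk <- paste(base[1] + offsets[r, 1], base[2] + offsets[r, 2],
                  base[3] + offsets[r, 3])
      nbr <- cells[[nk]]
      if (is.null(nbr)) next
      pr <- expand.grid(i = ids, j = nbr)
      pr <- pr[pr$i < pr$j, , drop = FALSE]
      pairs_i <- c(pairs_i, pr$i); pairs_j <- c(pairs_j, pr$j)
    }
  }
  if (length(pairs_i)) {
    d <- pos[pairs_i, , drop = FALSE] - pos[pairs_j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    keep <- r <= rc & r > 0
    if (any(keep)) {
      i <- pairs_i[keep]; j <- pairs_j[keep]
      coefv <- -params$k_EL * (r[keep] - params$r_0) / r[keep]
      f <- d[keep, , drop = FALSE] * coefv
      for (a in 1:3) {
        out[, a] <- out[, a] +
          as.numeric(tabulate_weighted(i, f[, a], n)) -
          as.numeric(tabulate_weighted(j, f[, a], n))
      }
    }
    coincident <- which(!r > 0)
    for (cc in coincident) {
      kick <- params$k_EL * params$r_0
      out[pairs_i[cc], 1] <- out[pairs_i[cc], 1] + kick
      out[pairs_j[cc], 1] <- out[pairs_j[cc], 1] - kick
    }
  }
  tibble::tibble(fx = out[, 1], fy = out[, 2], fz = out[, 3])
}

# Weighted bincount: sum w over entries with index i, length n.
tabulate_weighted <- function(i, w, n) {
  v <- numeric(n)
  agg <- rowsum(w, group = i)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

#' Seed a particle ensemble uniformly in the liquid
#'
#' @param n Number of particles.
#' @param geom A [reactor_geometry()].
#' @param cell A [cell_properties()].
#' @param seed RNG seed.
#' @return Tibble with columns `id`, `x`, `y`, `z`, `vx`, `vy`, `vz`, `mass`.
#' @export
seed_particles <- function(n = 1000, geom = reactor_geometry(),
                           cell = cell_properties(), seed = 1L) {
  set.seed(seed)
  p <- tibble::tibble(
    id = seq_len(n),
    x = runif(n, 0, geom$width),
    y = runif(n, 0, geom$thickness),
    z = runif(n, 0, geom$fill_height),
    vx = 0, vy = 0, vz = 0,
    mass = cell$initial_particle_mass
  )
  p
}

.reflect_axis <- function(pos, vel, lo, hi) {
  for (rep in 1:5) {
    below <- pos < lo; above <- pos > hi
    if (!any(below | above)) break
    pos[below] <- 2 * lo - pos[below]; vel[below] <- -vel[below]
    pos[above] <- 2 * hi - pos[above]; vel[above] <- -vel[above]
  }
  list(pos = pos, vel = vel)
}

#' Advance the particle ensemble one time step
#'
#' Inertial mode uses a semi-implicit update (drag treated implicitly, so
#' the stiff drag rate does not limit stability):
#' `v <- (v + dt (F_d v_fluid + a_g + F_el/m + F_ext/m)) / (1 + F_d dt)`,
#' then `x <- x + v dt`. Tracer mode sets the particle velocity to the
#' local fluid velocity plus the terminal settling correction, appropriate
#' when the relaxation time `1/F_d` is far below the time step. Wall
#' contacts with the liquid box are resolved by specular reflection.
#'
#' @param particles Ensemble tibble (see [seed_particles()]).
#' @param flow A [flow_field()].
#' @param fluid,cell Property records.
#' @param dt Time step (s), > 0.
#' @param geom A [reactor_geometry()].
#' @param mode `"tracer"` (default) or `"inertial"`.
#' @param interaction Optional [interaction_params()] (inertial mode).
#' @param f_ext Optional hook `function(particles, t)` returning a tibble of
#'   extra forces `fx`, `fy`, `fz` (N); defaults to zero.
#' @param t Current time (s).
#' @return Updated ensemble tibble.
#' @export
step_ensemble <- function(particles, flow, fluid, cell, dt,
                          geom = reactor_geometry(),
                          mode = c("tracer", "inertial"),
                          interaction = NULL, f_ext = NULL, t = 0) {
  mode <- match.arg(mode)
  if (dt <= 0) abort("`dt` must be > 0.")
  Fd <- drag_rate(fluid, cell)
  vset <- settling_velocity(fluid, cell)
  vf <- .flow_velocity(flow, geom, particles$x, particles$y, particles$z)

  if (mode == "tracer") {
    particles$vx <- vf$vx
    particles$vy <- vf$vy
    particles$vz <- vf$vz - vset
  } else {
    a_g <- -fluid$gravity *
      (cell$particle_density - fluid$fluid_density) / cell$particle_density
    ax <- Fd * vf$vx; ay <- Fd * vf$vy; az <- Fd * vf$vz + a_g
    if (!is.null(interaction) && interaction$k_EL > 0) {
      fe <- elastic_forces(particles, interaction)
      ax <- ax + fe$fx / particles$mass
      ay <- ay + fe$fy / particles$mass
      az <- az + fe$fz / particles$mass
    }
    if (!is.null(f_ext)) {
      fx <- f_ext(particles, t)
      ax <- ax + fx$fx / particles$mass
      ay <- ay + fx$fy / particles$mass
      az <- az + fx$fz / particles$mass
    }
    den <- 1 + Fd * dt
    particles$vx <- (particles$vx + dt * ax) / den
    particles$vy <- (particles$vy + dt * ay) / den
    particles$vz <- (particles$vz + dt * az) / den
  }
  rx <- .reflect_axis(particles$x + particles$vx * dt, particles$vx,
                      0, geom$width)
  ry <- .reflect_axis(particles$y + particles$vy * dt, particles$vy,
                      0, geom$thickness)
  rz <- .reflect_axis(particles$z + particles$vz * dt, particles$vz,
                      0, geom$fill_height)
  particles$x <- rx$pos; particles$vx <- rx$vel
  particles$y <- ry$pos; particles$vy <- ry$vel
  particles$z <- rz$pos; particles$vz <- rz$vel
  particles
}

#' Terminal settling speed
#'
#' Balance of gravity/buoyancy and Stokes drag:
#' `v_s = g (rho_p - rho) / (rho_p F_d)` (positive = sinking).
#'
#' @inheritParams drag_rate
#' @return Settling speed (m s^-1).
#' @export
settling_velocity <- function(fluid, cell) {
  Fd <- drag_rate(fluid, cell)
  if (Fd == 0) return(0)
  fluid$gravity *
    (cell$particle_density - fluid$fluid_density) /
    (cell$particle_density * Fd)
}

#' Trace an ensemble and record trajectories
#'
#' Integrates the ensemble for `duration` seconds and records positions
#' every `record_every` steps.
#'
#' @inheritParams step_ensemble
#' @param duration Simulated time (s).
#' @param record_every Record every k-th step.
#' @return Tibble with columns `time`, `id`, `x`, `y`, `z`.
#' @export
trace_particles <- function(particles, flow, fluid, cell, dt = 0.05,
                            duration = 60, geom = reactor_geometry(),
                            mode = "tracer", interaction = NULL,
                            record_every = 1L) {
  n_steps <- ceiling(duration / dt)
  recs <- vector("list", floor(n_steps / record_every) + 1)
  ri <- 1L
  recs[[ri]] <- dplyr::transmute(particles, time = 0, id = .data$id,
                                 x = .data$x, y = .data$y, z = .data$z)
  for (s in seq_len(n_steps)) {
    particles <- step_ensemble(particles, flow, fluid, cell, dt, geom,
                               mode = mode, interaction = interaction,
                               t = (s - 1) * dt)
    if (s %% record_every == 0) {
      ri <- ri + 1L
      recs[[ri]] <- dplyr::transmute(particles, time = s * dt, id = .data$id,
                                     x = .data$x, y = .data$y, z = .data$z)
    }
  }
  dplyr::bind_rows(recs[seq_len(ri)])
}

#' Per-cell perceived and absorbed light along trajectories
#'
#' The perceived intensity `I_p` is the gridded irradiance interpolated at
#' each particle position; the absorbed intensity is `I_ab = alpha_cell I_p`
#' with the cell absorptance.
#'
#' @param trajectories Tibble from [trace_particles()] (`time`, `id`, `x`,
#'   `y`, `z`).
#' @param light_field A `pbr_light_field` from [solve_dom_grid()], or a
#'   single non-negative number for a uniform field.
#' @param cell A [cell_properties()].
#' @return A `pbr_light_history`: tibble (`time`, `id`, `I_p`, `I_ab`).
#' @export
sample_light_history <- function(trajectories, light_field, cell) {
  stopifnot(inherits(cell, "pbr_cell"))
  Ip <- if (is.numeric(light_field) && length(light_field) == 1) {
    rep(light_field, nrow(trajectories))
  } else {
    light_field_interpolate(light_field, trajectories)
  }
  h <- dplyr::mutate(trajectories[c("time", "id")],
                     I_p = Ip, I_ab = cell$cell_absorptance * Ip)
  class(h) <- c("pbr_light_history", class(h))
  h
}

#' Summary statistics of a light history
#'
#' Reports the ensemble/time means of perceived and absorbed light, the
#' temporal fluctuation of the ensemble-mean perceived trace (standard
#' deviation over time as % of its time mean), and the fraction of
#' particle-time spent in each photic zone. Zone boundaries derive from the
#' kinetic constants: photo-limitation below `K_I,S`, photo-inhibition
#' above the growth optimum `sqrt(K_I,S K_I,i)`, photo-saturation between.
#'
#' @param history A `pbr_light_history` (or tibble with `time`, `I_p`,
#'   `I_ab`).
#' @param kinetics A [kinetic_params()] used for the zone thresholds.
#' @return A one-row tibble: `mean_Ip`, `mean_Iab`, `fluctuation_pct`,
#'   `frac_limitation`, `frac_saturation`, `frac_inhibition`.
#' @export
light_history_stats <- function(history, kinetics = kinetic_params(1)) {
  if (is.null(history) || nrow(history) == 0) {
    abort("`history` must be non-empty.")
  }
  lo <- kinetics$K_I_S
  hi <- sqrt(kinetics$K_I_S * kinetics$K_I_i)
  # when the optimum coincides with K_I_S the saturation zone is empty
  if (hi <= lo) hi <- lo * (1 + 1e-9)
  zone <- cut(history$I_p, c(-Inf, lo, hi, Inf),
              labels = c("limitation", "saturation", "inhibition"))
  ens <- history |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mIp = mean(.data$I_p), .groups = "drop")
  m <- mean(ens$mIp)
  fluct <- if (m > 0 && nrow(ens) > 1) stats::sd(ens$mIp) / m * 100 else 0
  fr <- as.numeric(table(zone)) / length(zone)
  tibble::tibble(mean_Ip = mean(history$I_p),
                 mean_Iab = mean(history$I_ab),
                 fluctuation_pct = fluct,
                 frac_limitation = fr[1],
                 frac_saturation = fr[2],
                 frac_inhibition = fr[3])
}
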