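# Prescribed divergence-free circulation flow: a sparger-driven
# recirculation roll in the width-height plane plus an azimuthal stirrer
# vortex near the bottom. Both components derive from stream functions, so
# the field is exactly solenoidal and satisfies no-penetration at the walls.

#' Prescribed circulation flow field
#'
#' Analytic surrogate for the reactor's mixing hydrodynamics. Component (a)
#' is a closed recirculation roll in the width-height plane from the stream
#' function `psi = A sin(pi x / W) sin(pi z / H_fill)` (A scaled so the peak
#' vertical speed equals `loop_speed`); component (b) is an azimuthal vortex
#' about the vertical stirrer axis built from a compactly supported stream
#' function: solid-body rotation out to `stirrer_radius`, a linear taper to
#' zero at `vortex_cutoff` (inside the walls), and a Gaussian vertical decay.
#'
#' @param loop_speed Peak vertical speed of the circulation roll (m s^-1).
#' @param stirrer_angular_speed Stirrer angular speed (rad s^-1).
#' @param stirrer_radius Solid-body core radius of the stirrer vortex (m);
#'   must stay inside `vortex_cutoff`.
#' @param stirrer_center 3-vector (m): axis position (x, y) and height (z)
#'   of the vortex core. Defaults to the vessel centreline just above the
#'   bottom (set when a geometry is supplied to the evaluators).
#' @param vortex_cutoff Radius at which the vortex velocity reaches zero (m).
#' @param vertical_decay Gaussian decay length of the vortex in z (m).
#' @return An object of class `pbr_flow`.
#' @export
flow_field <- function(loop_speed = 0.02,
                       stirrer_angular_speed = 2 * pi * 5,
                       stirrer_radius = 0.008,
                       stirrer_center = NULL,
                       vortex_cutoff = 0.0115,
                       vertical_decay = 0.02) {
  if (loop_speed < 0 || stirrer_angular_speed < 0) {
    abort("Speeds must be >= 0.")
  }
  if (stirrer_radius <= 0) abort("`stirrer_radius` must be > 0.")
  if (vortex_cutoff <= stirrer_radius) {
    abort("`vortex_cutoff` must exceed `stirrer_radius`.")
  }
  structure(list(loop_speed = loop_speed,
                 stirrer_angular_speed = stirrer_angular_speed,
                 stirrer_radius = stirrer_radius,
                 stirrer_center = stirrer_center,
                 vortex_cutoff = vortex_cutoff,
                 vertical_decay = vertical_decay),
            class = "pbr_flow")
}

.flow_center <- function(field, geom) {
  field$stirrer_center %||%
    c(geom$width / 2, geom$thickness / 2, geom$anchor_diameter / 2)
}

# Roll stream function and the vortex radial stream function F(r) with
# F'(r) = v_theta(r): omega r in the core, linear taper, then constant.
.roll_psi <- function(x, z, W, Hf, U) {
  if (Hf <= 0) return(x * 0)
  (U * W / pi) * sin(pi * x / W) * sin(pi * pmin(pmax(z, 0), Hf) / Hf) *
    (z >= 0 & z <= Hf)
}

.vortex_F <- function(r, omega, Rs, rc) {
  Fc_core <- omega * Rs^2 / 2
  taper <- function(r) {
    s <- (r - Rs)
    Fc_core + omega * Rs * s - omega * Rs * s^2 / (2 * (rc - Rs))
  }
  out <- ifelse(r <= Rs, omega * r^2 / 2, ifelse(r < rc, taper(r), taper(rc)))
  out
}

.vortex_vtheta <- function(r, omega, Rs, rc) {
  ifelse(r <= Rs, omega * r,
         ifelse(r < rc, omega * Rs * (rc - r) / (rc - Rs), 0))
}

.flow_velocity <- function(field, geom, x, y, z) {
  W <- geom$width; Hf <- geom$fill_height
  U <- field$loop_speed
  # Roll: u_x = d(psi)/dz, u_z = -d(psi)/dx, uniform in y.
  A <- U * W / pi
  inz <- z >= 0 & z <= Hf & Hf > 0
  vx <- ifelse(inz, A * sin(pi * x / W) * (pi / Hf) * cos(pi * z / Hf), 0)
  vz <- ifelse(inz, -A * (pi / W) * cos(pi * x / W) * sin(pi * z / Hf), 0)
  vy <- rep(0, length(x))
  # Stirrer vortex: azimuthal about the vertical axis through the centre.
  ctr <- .flow_center(field, geom)
  om <- field$stirrer_angular_speed
  if (om > 0) {
    dx <- x - ctr[1]; dy <- y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    g <- exp(-((z - ctr[3]) / field$vertical_decay)^2)
    vt <- .vortex_vtheta(r, om, field$stirrer_radius, field$vortex_cutoff) * g
    nz <- r > 0
    vx[nz] <- vx[nz] - vt[nz] * dy[nz] / r[nz]
    vy[nz] <- vy[nz] + vt[nz] * dx[nz] / r[nz]
  }
  list(vx = vx, vy = vy, vz = vz)
}

#' Fluid velocity at points in the liquid
#'
#' @param field A [flow_field()].
#' @param geom A [reactor_geometry()].
#' @param points Data frame with columns `x`, `y`, `z` (m) or a length-3
#'   numeric vector. All points must lie inside the liquid domain.
#' @param t Time (s); the prescribed field is steady, the argument exists
#'   for interface stability.
#' @return Tibble with columns `vx`, `vy`, `vz` (m s^-1).
#' @export
velocity_at <- function(field, geom, points, t = 0) {
  stopifnot(inherits(field, "pbr_flow"), inherits(geom, "pbr_geometry"))
  if (is.numeric(points) && is.null(dim(points))) {
    points <- tibble::tibble(x = points[1], y = points[2], z = points[3])
  }
  inside <- points$x >= 0 & points$x <= geom$width &
    points$y >= 0 & points$y <= geom$thickness &
    points$z >= 0 & points$z <= geom$fill_height
  if (any(!inside)) {
    abort(sprintf("%d point(s) outside the liquid domain.", sum(!inside)))
  }
  v <- .flow_velocity(field, geom, points$x, points$y, points$z)
  tibble::as_tibble(v)
}

#' Maximum discrete divergence of the flow field
#'
#' Central-difference divergence over interior grid nodes. The velocity
#' samples are themselves obtained by central differencing the two stream
#' functions with the same step, so the discrete divergence of the analytic
#' field vanishes to rounding error (the mixed difference operators
#' commute); a genuinely compressible `velocity_fun` is detected at its
#' true divergence.
#'
#' @param field A [flow_field()].
#' @param geom A [reactor_geometry()].
#' @param spacing Grid spacing (m).
#' @param velocity_fun Optional function `(x, y, z) -> list(vx, vy, vz)`
#'   replacing the packaged field (used e.g. as a negative control).
#' @return Maximum absolute divergence (s^-1) over interior nodes.
#' @export
divergence_check <- function(field, geom, spacing = 0.002,
                             velocity_fun = NULL) {
  stopifnot(inherits(geom, "pbr_geometry"))
  if (spacing <= 0) abort("`spacing` must be > 0.")
  h <- spacing
  xs <- seq(2 * h, geom$width - 2 * h, by = h)
  ys <- seq(2 * h, geom$thickness - 2 * h, by = h)
  zs <- seq(2 * h, geom$fill_height - 2 * h, by = h)
  if (!length(xs) || !length(ys) || !length(zs)) {
    abort("`spacing` too coarse for the liquid domain.")
  }
  g <- expand.grid(x = xs, y = ys, z = zs)

  if (is.null(velocity_fun)) {
    stopifnot(inherits(field, "pbr_flow"))
    ctr <- .flow_center(field, geom)
    psi_r <- function(x, z) .roll_psi(x, z, geom$width, geom$fill_height,
                                      field$loop_speed)
    # Negated so vx = d(psi)/dy, vy = -d(psi)/dx gives the same
    # counter-clockwise rotation as the analytic evaluator.
    psi_v <- function(x, y, z) {
      r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
      -.vortex_F(r, field$stirrer_angular_speed, field$stirrer_radius,
                 field$vortex_cutoff) *
        exp(-((z - ctr[3]) / field$vertical_decay)^2)
    }
    velocity_fun <- function(x, y, z) {
      list(
        vx = (psi_r(x, z + h) - psi_r(x, z - h)) / (2 * h) +
          (psi_v(x, y + h, z) - psi_v(x, y - h, z)) / (2 * h),
        vy = -(psi_v(x + h, y, z) - psi_v(x - h, y, z)) / (2 * h),
        vz = -(psi_r(x + h, z) - psi_r(x - h, z)) / (2 * h)
      )
    }
  }
  vxp <- velocity_fun(g$x + h, g$y, g$z)$vx
  vxm <- velocity_fun(g$x - h, g$y, g$z)$vx
  vyp <- velocity_fun(g$x, g$y + h, g$z)$vy
  vym <- velocity_fun(g$x, g$y - h, g$z)$vy
  vzp <- velocity_fun(g$x, g$y, g$z + h)$vz
  vzm <- velocity_fun(g$x, g$y, g$z - h)$vz
  div <- (vxp - vxm + vyp - vym + vzp - vzm) / (2 * h)
  max(abs(div))
}
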