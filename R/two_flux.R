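# Two-flux (Schuster-Schwarzschild) radiative transfer through a stack of
# plane-parallel layers. Forward and backward irradiance streams I+ and I-
# satisfy, with alpha = kappa + f*sigma and beta = f*sigma (f = fraction of
# scattering redirected into the opposite stream),
#
#   dI+/dy = -alpha I+ + beta I-
#   dI-/dy = -beta  I+ + alpha I-
#
# solved per layer with the analytic 2x2 matrix exponential and flux
# continuity at interfaces. With sigma = 0 this reduces exactly to
# Beer-Lambert attenuation exp(-kappa L).

.two_flux_layer_matrix <- function(kappa, sigma, L, f) {
  alpha <- kappa + f * sigma
  beta <- f * sigma
  A <- matrix(c(-alpha, -beta, beta, alpha), 2, 2) # column-major
  g2 <- alpha^2 - beta^2
  if (g2 <= 0) return(diag(2) + L * A)
  g <- sqrt(g2)
  cosh(g * L) * diag(2) + (sinh(g * L) / g) * A
}

#' Two-flux light transmission through layered media
#'
#' Solves the coupled forward/backward stream equations through an ordered
#' stack of homogeneous layers, with the forward stream entering the first
#' layer and no backward stream entering the last.
#'
#' @param layers A data frame with one row per layer (ordered along the
#'   light path) and columns `thickness` (m), `kappa` (absorption, m^-1),
#'   `sigma` (scattering, m^-1) and optionally `domain` (label used in the
#'   absorption budget).
#' @param incident Incident forward irradiance (W m^-2); results are also
#'   reported as fractions of this.
#' @param backscatter_fraction Fraction of scattered power redirected into
#'   the opposite stream (0.5 for isotropic scattering).
#' @param profile_points Sample points per layer for the depth profile.
#' @return A `pbr_two_flux` list with elements `profile` (tibble: `y`,
#'   `I_fwd`, `I_bwd`, `G = I_fwd + I_bwd`), `transmitted` and
#'   `back_scattered` fractions, `absorbed` (tibble: `domain`, `fraction`),
#'   and `incident`.
#' @examples
#' tf <- solve_two_flux_1d(data.frame(thickness = 0.024, kappa = 4, sigma = 0))
#' tf$transmitted # exp(-0.096)
#' @export
solve_two_flux_1d <- function(layers, incident = 1,
                              backscatter_fraction = 0.5,
                              profile_points = 25) {
  layers <- tibble::as_tibble(layers)
  if (nrow(layers) == 0) abort("`layers` must contain at least one layer.")
  if (!all(c("thickness", "kappa") %in% names(layers))) {
    abort("`layers` needs columns `thickness` and `kappa`.")
  }
  if (!"sigma" %in% names(layers)) layers$sigma <- 0
  if (!"domain" %in% names(layers)) {
    layers$domain <- paste0("layer_", seq_len(nrow(layers)))
  }
  if (any(layers$thickness <= 0)) abort("Layer thicknesses must be > 0.")
  if (any(layers$kappa < 0) || any(layers$sigma < 0)) {
    abort("Optical coefficients must be >= 0.")
  }
  if (incident < 0) abort("`incident` must be >= 0.")
  f <- backscatter_fraction

  n <- nrow(layers)
  mats <- purrr::map(seq_len(n), function(i) {
    .two_flux_layer_matrix(layers$kappa[i], layers$sigma[i],
                           layers$thickness[i], f)
  })
  M <- Reduce(`%*%`, mats) # v(L) = M_n ... M_1 v(0)
  # Boundary conditions: I+(0) = incident, I-(L) = 0.
  B <- if (abs(M[2, 2]) < .Machine$double.eps) 0 else -M[2, 1] / M[2, 2]
  v0 <- c(1, B)

  # Interface states and per-layer absorption from the net-flux drop.
  states <- vector("list", n + 1)
  states[[1]] <- v0
  for (i in seq_len(n)) states[[i + 1]] <- as.vector(mats[[i]] %*% states[[i]])
  net_flux <- vapply(states, function(v) v[1] - v[2], numeric(1))
  absorbed <- net_flux[seq_len(n)] - net_flux[seq_len(n) + 1]

  y0 <- c(0, cumsum(layers$thickness))
  profile <- purrr::map_dfr(seq_len(n), function(i) {
    s <- seq(0, layers$thickness[i], length.out = profile_points)
    vals <- vapply(s, function(ds) {
      as.vector(.two_flux_layer_matrix(layers$kappa[i], layers$sigma[i],
                                       ds, f) %*% states[[i]])
    }, numeric(2))
    tibble::tibble(y = y0[i] + s, I_fwd = vals[1, ] * incident,
                   I_bwd = vals[2, ] * incident)
  })
  profile$G <- profile$I_fwd + profile$I_bwd

  absorbed_tbl <- tibble::tibble(domain = layers$domain,
                                 fraction = absorbed) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")

  structure(list(profile = profile,
                 transmitted = states[[n + 1]][1],
                 back_scattered = B,
                 absorbed = absorbed_tbl,
                 incident = incident),
            class = "pbr_two_flux")
}

#' One-dimensional panel light solve for the assembled vessel
#'
#' Builds the glass / liquid / glass layer stack from a geometry, optical
#' property set and source, applies the front-interface reflectance, and
#' runs [solve_two_flux_1d()]. The liquid layer combines medium, biomass and
#' bubble coefficients; its absorbed fraction is apportioned among those
#' domains by their share of the absorption coefficient.
#'
#' @param geom A [reactor_geometry()].
#' @param optics An [optical_properties()] record.
#' @param source A [light_source()].
#' @param ... Passed to [solve_two_flux_1d()].
#' @return A `pbr_panel_light` list: `profile` (depth profile through the
#'   cavity, y measured from the inner front glass face), `I_in` (W m^-2 at
#'   the panel), `I_out` (outlet irradiance, W m^-2), `I_out_uE`,
#'   `transmitted`, `back_scattered`, `absorbed` (tibble by domain:
#'   glass/medium/biomass/bubbles), `mean_G` (volume-averaged irradiance in
#'   the liquid, W m^-2).
#' @export
panel_light_1d <- function(geom, optics, source, ...) {
  stopifnot(inherits(geom, "pbr_geometry"), inherits(optics, "pbr_optics"),
            inherits(source, "pbr_source"))
  E0 <- emitted_intensity(source)
  R <- optics$glass_reflectance
  kap_liq <- optics$kappa_medium + optics$kappa_biomass + optics$kappa_bubbles
  sig_liq <- optics$sigma_medium + optics$sigma_biomass + optics$sigma_bubbles
  layers <- tibble::tibble(
    thickness = c(geom$glass_thickness, geom$thickness, geom$glass_thickness),
    kappa = c(optics$kappa_glass, kap_liq, optics$kappa_glass),
    sigma = c(optics$sigma_glass, sig_liq, optics$sigma_glass),
    domain = c("glass", "liquid", "glass")
  )
  tf <- solve_two_flux_1d(layers, incident = 1, ...)

  enter <- 1 - R
  absorbed <- tf$absorbed
  liq_frac <- absorbed$fraction[absorbed$domain == "liquid"] * enter
  glass_frac <- absorbed$fraction[absorbed$domain == "glass"] * enter
  shares <- if (kap_liq > 0) {
    c(medium = optics$kappa_medium, biomass = optics$kappa_biomass,
      bubbles = optics$kappa_bubbles) / kap_liq
  } else c(medium = 0, biomass = 0, bubbles = 0)
  budget <- tibble::tibble(
    domain = c("glass", "medium", "biomass", "bubbles"),
    fraction = c(glass_frac, liq_frac * shares[["medium"]],
                 liq_frac * shares[["biomass"]], liq_frac * shares[["bubbles"]])
  )

  liq <- dplyr::filter(tf$profile,
                       .data$y >= geom$glass_thickness,
                       .data$y <= geom$glass_thickness + geom$thickness)
  profile <- dplyr::mutate(tf$profile, y = .data$y - geom$glass_thickness,
                           I_fwd = .data$I_fwd * enter * E0,
                           I_bwd = .data$I_bwd * enter * E0,
                           G = .data$G * enter * E0)
  I_out <- tf$transmitted * enter * E0
  liq_in <- profile$I_fwd[which.min(abs(profile$y))]
  liq_out <- profile$I_fwd[which.min(abs(profile$y - geom$thickness))]
  structure(list(profile = profile,
                 I_liq_in = liq_in, I_liq_out = liq_out,
                 I_in = E0,
                 I_out = I_out,
                 I_out_uE = wm2_to_microE(I_out, source$wavelength),
                 transmitted = tf$transmitted * enter,
                 back_scattered = R + tf$back_scattered * enter,
                 absorbed = budget,
                 mean_G = mean(liq$G) * enter * E0,
                 source = source),
            class = "pbr_panel_light")
}
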