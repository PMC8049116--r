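# Optical property records, the calibration-dependent LED source model and
# the biomass-dependent absorption law.

#' Default biomass absorption power-law constants
#'
#' The absorption coefficient of the culture follows a power law
#' kappa(X) = a * X^b in the biomass concentration X (gDCW/L). The default
#' constants are obtained by solving the two literature anchor points adopted
#' for this organism -- kappa = 1.34 m^-1 at X = 0.1 gDCW/L and
#' kappa = 4 m^-1 at X = 2 gDCW/L -- exactly.
#'
#' @return Named numeric vector with elements `a` (m^-1 per (gDCW/L)^b)
#'   and `b` (dimensionless).
#' @export
absorption_law_defaults <- function() {
  b <- log(4 / 1.34) / log(2 / 0.1)
  a <- 1.34 / 0.1^b
  c(a = a, b = b)
}

#' Biomass-dependent absorption coefficient
#'
#' kappa(X) = a * X^b: strictly increasing in X for positive constants and
#' zero at zero biomass. With the default constants it reproduces
#' ~1.34 m^-1 at 0.1 gDCW/L and ~4 m^-1 at 2 gDCW/L.
#'
#' @param X Biomass concentration (gDCW/L), vectorised, >= 0.
#' @param a,b Power-law constants; defaults from [absorption_law_defaults()].
#' @return Absorption coefficient in m^-1.
#' @examples
#' biomass_absorption_coefficient(c(0.1, 2))
#' @export
biomass_absorption_coefficient <- function(X,
                                           a = absorption_law_defaults()[["a"]],
                                           b = absorption_law_defaults()[["b"]]) {
  if (!is.numeric(X) || any(X < 0)) abort("`X` must be non-negative (gDCW/L).")
  a * X^b
}

#' Per-domain optical properties
#'
#' Absorption (`kappa_*`, m^-1) and scattering (`sigma_*`, m^-1) coefficients
#' for the optically active domains of the vessel, plus a single glass
#' interface reflectance. Steel (walls, probes, sparger, stirrer) is treated
#' as opaque. The default abiotic medium coefficient is set so that the
#' abiotic liquid-phase loss over the 24 mm light path is small (order 6%);
#' bubbles contribute scattering only.
#'
#' @param kappa_glass,sigma_glass Glass absorption/scattering (m^-1).
#' @param kappa_medium,sigma_medium Cell-free medium coefficients (m^-1).
#' @param kappa_biomass,sigma_biomass Biomass coefficients (m^-1); the
#'   absorption part is usually supplied via
#'   [biomass_absorption_coefficient()] at the current biomass.
#' @param kappa_bubbles,sigma_bubbles Bubble-phase coefficients (m^-1).
#' @param glass_reflectance Fraction of incident light reflected at the
#'   front glass interface, in `[0, 1)`.
#' @return An object of class `pbr_optics`.
#' @export
optical_properties <- function(kappa_glass = 1.5, sigma_glass = 0,
                               kappa_medium = 2.5, sigma_medium = 0,
                               kappa_biomass = 0, sigma_biomass = 0,
                               kappa_bubbles = 0, sigma_bubbles = 1.0,
                               glass_reflectance = 0.04) {
  vals <- c(kappa_glass, sigma_glass, kappa_medium, sigma_medium,
            kappa_biomass, sigma_biomass, kappa_bubbles, sigma_bubbles)
  if (any(vals < 0)) abort("Optical coefficients must be >= 0.")
  if (glass_reflectance < 0 || glass_reflectance >= 1) {
    abort("`glass_reflectance` must lie in [0, 1).")
  }
  structure(list(kappa_glass = kappa_glass, sigma_glass = sigma_glass,
                 kappa_medium = kappa_medium, sigma_medium = sigma_medium,
                 kappa_biomass = kappa_biomass, sigma_biomass = sigma_biomass,
                 kappa_bubbles = kappa_bubbles, sigma_bubbles = sigma_bubbles,
                 glass_reflectance = glass_reflectance),
            class = "pbr_optics")
}

#' Replace the biomass absorption coefficient for a given biomass
#'
#' Convenience helper: returns a copy of `optics` with `kappa_biomass` set
#' from the power law at biomass `X`.
#'
#' @param optics A [optical_properties()] record.
#' @param X Biomass concentration (gDCW/L).
#' @param a,b Power-law constants.
#' @return Updated `pbr_optics`.
#' @export
with_biomass <- function(optics, X,
                         a = absorption_law_defaults()[["a"]],
                         b = absorption_law_defaults()[["b"]]) {
  stopifnot(inherits(optics, "pbr_optics"))
  optics$kappa_biomass <- biomass_absorption_coefficient(X, a, b)
  optics
}

#' Default LED calibration factors
#'
#' Multiplicative factors mapping the software light setpoint to the
#' intensity actually emitted at the panel, one per calibration case:
#' case 1 calibrates with the sensor on the panel (no air gap, factor 1);
#' cases 2 and 3 calibrate with the sensor 1 cm away (five-point average and
#' central point respectively), so the panel must emit more to reach the
#' prescribed reading. Values are configurable; the ordering c1 < c2 ~ c3
#' is the physically mandated one.
#' @export
CALIBRATION_FACTORS <- c(`1` = 1.0, `2` = 1.25, `3` = 1.25)

#' LED light source
#'
#' @param setpoint Software light setpoint in uE.
#' @param calibration_case Calibration case, 1, 2 or 3.
#' @param calibration_factor Override of the per-case default factor.
#' @param wavelength Emission wavelength (m).
#' @return An object of class `pbr_source`.
#' @export
light_source <- function(setpoint, calibration_case = 1,
                         calibration_factor = NULL,
                         wavelength = PBR_WAVELENGTH) {
  if (!is.numeric(setpoint) || setpoint < 0) {
    abort("`setpoint` must be a non-negative photon flux in uE.")
  }
  if (!calibration_case %in% c(1, 2, 3)) {
    abort("`calibration_case` must be 1, 2 or 3.")
  }
  ck <- calibration_factor %||%
    CALIBRATION_FACTORS[[as.character(calibration_case)]]
  if (ck <= 0) abort("`calibration_factor` must be > 0.")
  structure(list(setpoint = setpoint,
                 calibration_case = as.integer(calibration_case),
                 calibration_factor = ck, wavelength = wavelength),
            class = "pbr_source")
}

#' Emitted intensity at the inner glass face
#'
#' The calibration factor scales the setpoint to the irradiance the LED
#' panel actually delivers at the vessel face, converted to W m^-2.
#'
#' @param source A [light_source()].
#' @return Irradiance in W m^-2.
#' @export
emitted_intensity <- function(source) {
  stopifnot(inherits(source, "pbr_source"))
  microE_to_wm2(source$calibration_factor * source$setpoint,
                source$wavelength)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
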