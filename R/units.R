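# Photon-unit conversions. Internals are SI (W m^-2); the micromole-photon
# flux unit ("microEinstein", uE = umol photons m^-2 s^-1) appears only at
# interfaces, because the kinetic constants are expressed in W m^-2 while
# LED setpoints and sensors speak uE.

#  CODATA 2018 exact constants
.PLANCK <- 6.62607015e-34     # J s
.C_LIGHT <- 299792458         # m s^-1
.AVOGADRO <- 6.02214076e23    # mol^-1

#' Default LED wavelength
#'
#' Peak wavelength of the orange-red LED panel driving the reactor, in metres.
#' @export
PBR_WAVELENGTH <- 636e-9

#' Energy carried by one micromole of photons
#'
#' @param wavelength Photon wavelength in metres.
#' @return Energy in joules per micromole of photons.
#' @examples
#' photon_energy_umol(636e-9) # ~0.188 J/umol
#' @export
photon_energy_umol <- function(wavelength = PBR_WAVELENGTH) {
  if (!is.numeric(wavelength) || any(wavelength <= 0)) {
    abort("`wavelength` must be positive (metres).")
  }
  .PLANCK * .C_LIGHT / wavelength * .AVOGADRO * 1e-6
}

#' Convert photon flux (uE) to irradiance (W m^-2)
#'
#' One uE is one umol photons m^-2 s^-1. For monochromatic light the energy
#' flux is the photon flux times the photon energy, so the conversion factor
#' at 636 nm is ~0.18810 W m^-2 per uE.
#'
#' @param I Photon flux in uE (vectorised, must be >= 0).
#' @param wavelength Wavelength in metres.
#' @return Irradiance in W m^-2.
#' @examples
#' microE_to_wm2(300) # ~56.4 W m^-2
#' @export
microE_to_wm2 <- function(I, wavelength = PBR_WAVELENGTH) {
  if (!is.numeric(I) || any(I < 0)) abort("`I` must be non-negative (uE).")
  I * photon_energy_umol(wavelength)
}

#' Convert irradiance (W m^-2) to photon flux (uE)
#'
#' Inverse of [microE_to_wm2()]; the two compose to the identity.
#'
#' @inheritParams microE_to_wm2
#' @param I Irradiance in W m^-2 (vectorised, must be >= 0).
#' @return Photon flux in uE.
#' @export
wm2_to_microE <- function(I, wavelength = PBR_WAVELENGTH) {
  if (!is.numeric(I) || any(I < 0)) abort("`I` must be non-negative (W m^-2).")
  I / photon_energy_umol(wavelength)
}
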