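# Synthetic experimental campaigns: the light staircase run under each
# calibration case with replicated, noisy observables and a known ground
# truth, so every estimator can be exercised without laboratory data.

#' Staircase campaign design
#'
#' The default design mirrors the physical experiment: seven setpoints
#' from 50 to 1,200 uE held for 24 h each, three replicates for
#' calibration case 1 and two for cases 2 and 3, with small multiplicative
#' measurement noise.
#'
#' @param setpoints_uE Strictly increasing light setpoints (uE).
#' @param hold_hours Hold duration per step (h).
#' @param cases Calibration cases run.
#' @param replicates Replicate count per case (recycled).
#' @param noise Named numeric: multiplicative log-normal sigma for `mu`,
#'   `dO2` and `I_out`.
#' @param seed RNG seed for the noise draws.
#' @return An object of class `pbr_campaign`.
#' @export
campaign <- function(setpoints_uE = c(50, 100, 200, 300, 500, 950, 1200),
                     hold_hours = 24,
                     cases = c(1, 2, 3),
                     replicates = c(3, 2, 2),
                     noise = c(mu = 0.02, dO2 = 0.02, I_out = 0.01),
                     seed = 1L) {
  if (any(diff(setpoints_uE) <= 0)) {
    abort("`setpoints_uE` must be strictly increasing.")
  }
  if (hold_hours <= 0) abort("`hold_hours` must be > 0.")
  if (any(noise < 0)) abort("Noise sigmas must be >= 0.")
  replicates <- rep(replicates, length.out = length(cases))
  structure(list(setpoints_uE = setpoints_uE, hold_hours = hold_hours,
                 cases = cases, replicates = replicates,
                 noise = noise, seed = as.integer(seed)),
            class = "pbr_campaign")
}

#' Generate a synthetic campaign dataset from known ground truth
#'
#' Runs the forward model per light step in fast mode -- the turbidostat
#' holds the biomass at the band centre, so each step's steady state is
#' evaluated directly: the biomass-dependent light field gives the
#' effective irradiance, the Haldane law the growth rate, and the lumped
#' oxygen balance the steady dissolved oxygen. Multiplicative log-normal
#' noise with the campaign's sigmas is then applied; the draw order is
#' fixed, so a given seed always yields the same dataset.
#'
#' @param truth List with components `kinetics` (a [kinetic_params()]),
#'   `absorption` (named vector `a`, `b`), `calibration_factors` (named by
#'   case), `optics` (abiotic [optical_properties()]), `gdcw_per_od`,
#'   `oxygen` (an [oxygen_params()]). Missing components fall back to the
#'   package defaults.
#' @param design A [campaign()].
#' @param geom A [reactor_geometry()].
#' @param od_center Turbidostat band centre (OD730).
#' @return A `pbr_campaign_data` list: `observations` (tibble: `step`,
#'   `setpoint_uE`, `case`, `replicate`, `I_eff_Wm2`, `mu_h`, `dO2`,
#'   `I_out_uE`), `abiotic` (tibble: `setpoint_uE`, `case`, `replicate`,
#'   `I_out_uE`), `truth`, and `design`.
#' @export
generate_campaign <- function(truth = list(), design = campaign(),
                              geom = reactor_geometry(), od_center = 0.4) {
  stopifnot(inherits(design, "pbr_campaign"))
  kin <- truth$kinetics %||% kinetic_params_case(1)
  ab <- truth$absorption %||% absorption_law_defaults()
  cal <- truth$calibration_factors %||% CALIBRATION_FACTORS
  optics <- truth$optics %||% optical_properties()
  gdcw <- truth$gdcw_per_od %||% 0.25
  oxy <- truth$oxygen %||% oxygen_params()
  X_held <- od_center * gdcw

  sg <- design$noise[["mu"]]; so <- design$noise[["dO2"]]
  si <- design$noise[["I_out"]]
  set.seed(design$seed)

  obs <- list(); abio <- list()
  for (ci in seq_along(design$cases)) {
    cs <- design$cases[ci]
    ck <- cal[[as.character(cs)]] %||% cal[[ci]]
    for (rep_i in seq_len(design$replicates[ci])) {
      for (s in seq_along(design$setpoints_uE)) {
        src <- light_source(design$setpoints_uE[s], cs,
                            calibration_factor = ck)
        biotic <- panel_light_1d(geom, with_biomass(optics, X_held,
                                                    ab[["a"]], ab[["b"]]),
                                 src)
        abiotic <- panel_light_1d(geom, optics, src)
        mu <- growth_rate(biotic$mean_G, kin)
        dO2 <- oxy$dO2_sat + oxy$Y_O2 * mu * X_held / oxy$k_La
        obs[[length(obs) + 1]] <- tibble::tibble(
          step = s, setpoint_uE = design$setpoints_uE[s],
          case = cs, replicate = rep_i,
          I_eff_Wm2 = biotic$mean_G,
          mu_h = mu * exp(rnorm(1, 0, sg)),
          dO2 = dO2 * exp(rnorm(1, 0, so)),
          I_out_uE = biotic$I_out_uE * exp(rnorm(1, 0, si)),
          gdcw_per_od = gdcw
        )
        abio[[length(abio) + 1]] <- tibble::tibble(
          setpoint_uE = design$setpoints_uE[s], case = cs,
          replicate = rep_i,
          I_out_uE = abiotic$I_out_uE * exp(rnorm(1, 0, si))
        )
      }
    }
  }
  structure(list(observations = dplyr::bind_rows(obs),
                 abiotic = dplyr::bind_rows(abio),
                 truth = list(kinetics = kin, absorption = ab,
                              calibration_factors = cal, optics = optics,
                              gdcw_per_od = gdcw, oxygen = oxy),
                 design = design),
            class = "pbr_campaign_data")
}

#' @export
print.pbr_campaign_data <- function(x, ...) {
  cat(sprintf("<pbr_campaign_data> %d observations, %d abiotic readings\n",
              nrow(x$observations), nrow(x$abiotic)))
  invisible(x)
}
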