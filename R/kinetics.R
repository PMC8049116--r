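# Haldane-type photo-growth kinetics, lumped dissolved-oxygen balance and
# turbidostat dilution control.

#' Haldane photo-growth kinetic parameters
#'
#' The growth law is the Haldane/Andrews substrate-inhibition form in the
#' irradiance I (W m^-2):
#' `mu(I) = mu_max I / (K_I_S + I + I^2 / K_I_i)`,
#' with a light-saturation constant `K_I_S`, a photo-inhibition constant
#' `K_I_i`, and maximum `mu_max / (1 + 2 sqrt(K_I_S / K_I_i))` attained at
#' `I* = sqrt(K_I_S K_I_i)`.
#'
#' @param mu_max Maximum specific growth rate (h^-1).
#' @param K_I_S Light-saturation constant (W m^-2).
#' @param K_I_i Photo-inhibition constant (W m^-2).
#' @return An object of class `pbr_kinetics`.
#' @export
kinetic_params <- function(mu_max = 0.364, K_I_S = 114.5, K_I_i = 72.46) {
  if (mu_max <= 0 || K_I_S <= 0 || K_I_i <= 0) {
    abort("All kinetic parameters must be > 0.")
  }
  structure(list(mu_max = mu_max, K_I_S = K_I_S, K_I_i = K_I_i),
            class = "pbr_kinetics")
}

#' Fitted kinetic parameter sets for the three calibration cases
#'
#' Returns the Haldane constants fitted to the staircase experiment under
#' each LED calibration case; the apparent kinetics differ between cases
#' because the calibration changes the light actually delivered at a given
#' setpoint.
#'
#' @param case Calibration case: 1, 2 or 3.
#' @return A [kinetic_params()] object.
#' @export
kinetic_params_case <- function(case) {
  switch(as.character(case),
         "1" = kinetic_params(mu_max = 0.364, K_I_S = 114.5, K_I_i = 72.46),
         "2" = kinetic_params(mu_max = 0.221, K_I_S = 43.32, K_I_i = 114.9),
         "3" = kinetic_params(mu_max = 0.265, K_I_S = 55.39, K_I_i = 82.64),
         abort("`case` must be 1, 2 or 3."))
}

#' Haldane specific growth rate
#'
#' @param I Irradiance (W m^-2), vectorised, >= 0.
#' @param params A [kinetic_params()].
#' @return Specific growth rate (h^-1).
#' @examples
#' p <- kinetic_params_case(1)
#' growth_rate(sqrt(p$K_I_S * p$K_I_i), p) # the maximum of the law
#' @export
growth_rate <- function(I, params) {
  stopifnot(inherits(params, "pbr_kinetics"))
  if (!is.numeric(I) || any(I < 0)) abort("`I` must be non-negative (W m^-2).")
  params$mu_max * I / (params$K_I_S + I + I^2 / params$K_I_i)
}

#' Culture state record
#'
#' @param X Biomass concentration (gDCW/L).
#' @param OD730 Optical density at 730 nm.
#' @param dO2 Dissolved oxygen (% air saturation).
#' @param time Culture time (h).
#' @return An object of class `pbr_state`.
#' @export
culture_state <- function(X = 0.1, OD730 = 0.4, dO2 = 100, time = 0) {
  if (X < 0 || OD730 < 0) abort("`X` and `OD730` must be >= 0.")
  structure(list(X = X, OD730 = OD730, dO2 = dO2, time = time),
            class = "pbr_state")
}

#' Lumped dissolved-oxygen parameters
#'
#' A single well-mixed oxygen balance stands in for the detailed gas-liquid
#' mass-transfer system: `d(dO2)/dt = Y_O2 mu X - k_La (dO2 - dO2_sat)`.
#' Defaults place the steady state in a plausible 100-160% air-saturation
#' band over the observed growth-rate range.
#'
#' @param Y_O2 Oxygen yield, % air saturation per (gDCW/L) per unit mu.
#' @param k_La Volumetric transfer coefficient (h^-1).
#' @param dO2_sat Air-saturation level (%).
#' @return An object of class `pbr_oxygen`.
#' @export
oxygen_params <- function(Y_O2 = 8000, k_La = 5, dO2_sat = 100) {
  if (k_La <= 0) abort("`k_La` must be > 0.")
  structure(list(Y_O2 = Y_O2, k_La = k_La, dO2_sat = dO2_sat),
            class = "pbr_oxygen")
}

#' Advance dissolved oxygen one step
#'
#' Exact exponential update of the linear balance toward its steady state
#' `dO2_sat + Y_O2 mu X / k_La`.
#'
#' @param dO2 Current dissolved oxygen (% air saturation).
#' @param mu Current specific growth rate (h^-1).
#' @param X Current biomass (gDCW/L).
#' @param params An [oxygen_params()].
#' @param dt Time step (h), > 0.
#' @return Updated dissolved oxygen.
#' @export
oxygen_step <- function(dO2, mu, X, params, dt) {
  stopifnot(inherits(params, "pbr_oxygen"))
  if (dt <= 0) abort("`dt` must be > 0.")
  target <- params$dO2_sat + params$Y_O2 * mu * X / params$k_La
  target + (dO2 - target) * exp(-params$k_La * dt)
}

#' Turbidostat dilution step
#'
#' Implements the densitometer band control: when OD730 exceeds
#' `center * (1 + half_width)` the culture is diluted multiplicatively down
#' to `center * (1 - half_width)`; biomass and OD scale by the same factor.
#'
#' @param state A [culture_state()].
#' @param center Band centre OD (default 0.4).
#' @param half_width Relative half-width (default 0.025, i.e. 0.4 +/- 2.5%).
#' @return List with `state` (possibly diluted) and `dilution` (removed
#'   volume fraction; 0 when no dilution fired).
#' @export
turbidostat_step <- function(state, center = 0.4, half_width = 0.025) {
  stopifnot(inherits(state, "pbr_state"))
  if (half_width <= 0) abort("`half_width` must be > 0.")
  upper <- center * (1 + half_width)
  lower <- center * (1 - half_width)
  if (state$OD730 > upper) {
    f <- lower / state$OD730
    state$X <- state$X * f
    state$OD730 <- lower
    list(state = state, dilution = 1 - f)
  } else {
    list(state = state, dilution = 0)
  }
}

#' Growth rate from the OD slope between dilutions
#'
#' Least-squares slope of `ln(OD)` versus time. If a `window` column marks
#' inter-dilution segments, the slope is estimated per window (windows with
#' at least 3 samples) and averaged.
#'
#' @param od A data frame with columns `time` (h) and `OD730`, optionally
#'   `window`.
#' @return Estimated growth rate (h^-1).
#' @export
growth_rate_from_od_slope <- function(od) {
  od <- tibble::as_tibble(od)
  if (!all(c("time", "OD730") %in% names(od))) {
    abort("`od` needs columns `time` and `OD730`.")
  }
  slope1 <- function(d) {
    if (nrow(d) < 3) return(NA_real_)
    unname(coef(lm(log(OD730) ~ time, data = d))[2])
  }
  if ("window" %in% names(od)) {
    sl <- od |>
      dplyr::group_by(.data$window) |>
      dplyr::group_map(~ slope1(.x))
    sl <- unlist(sl)
    sl <- sl[!is.na(sl)]
    if (!length(sl)) abort("Need at least 3 samples in some dilution window.")
    mean(sl)
  } else {
    if (nrow(od) < 3) abort("Need at least 3 samples between dilutions.")
    slope1(od)
  }
}
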