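# Parameter estimation: Haldane kinetic constants, the biomass absorption
# power law, and the LED calibration factors. All fitters return a
# `pbr_fit` object with broom-style tidy()/glance() methods.

.new_fit <- function(model, estimates, rss, converged, n_starts, seed,
                     data, flags = character(0), extra = list()) {
  structure(c(list(model = model, estimates = estimates, rss = rss,
                   converged = converged, n_starts = n_starts, seed = seed,
                   data = data, flags = flags), extra),
            class = "pbr_fit")
}

#' @export
print.pbr_fit <- function(x, ...) {
  cat(sprintf("<pbr_fit> %s fit (RSS %.4g, %s)\n", x$model, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy pbr_fit
#' @export
tidy.pbr_fit <- function(x, ...) x$estimates

#' @method glance pbr_fit
#' @export
glance.pbr_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, converged = x$converged,
                 n_starts = x$n_starts, seed = x$seed,
                 n_obs = nrow(x$data),
                 flags = paste(x$flags, collapse = ";"))
}

.pick_col <- function(data, candidates, what) {
  hit <- candidates[candidates %in% names(data)]
  if (!length(hit)) {
    abort(sprintf("Input table needs a %s column (one of: %s).",
                  what, paste(candidates, collapse = ", ")))
  }
  data[[hit[1]]]
}

#' Fit Haldane photo-growth kinetics to irradiance-growth data
#'
#' Nonlinear least squares of
#' `mu(I) = mu_max I / (K_I_S + I + I^2/K_I_i)` with multi-start
#' Levenberg-Marquardt in log-parameter space (positivity enforced by
#' construction; starts drawn log-uniformly over the bounds with a fixed
#' seed). Returns the best of all starts.
#'
#' @param data Data frame with an irradiance column (`I_Wm2`, or `I_uE`
#'   converted internally at the default wavelength) and a growth-rate
#'   column (`mu_h` or `mu`, h^-1).
#' @param n_starts Number of multi-start draws.
#' @param seed RNG seed for start generation (determinism contract).
#' @param bounds Named list with elements `mu_max`, `K` (each a length-2
#'   range) bounding the log-uniform starts and the divergence check.
#' @param loss `"absolute"` (default; symmetric error bars) or
#'   `"relative"` residuals.
#' @return A `pbr_fit` with terms `mu_max` (h^-1), `K_I_S`, `K_I_i`
#'   (W m^-2). Flags: `no_interior_maximum` when the observed rates are
#'   monotone in I, `K_I_i_at_bound` when inhibition is unidentifiable.
#' @export
fit_haldane <- function(data, n_starts = 16, seed = 1L,
                        bounds = list(mu_max = c(1e-3, 2), K = c(1, 1e3)),
                        loss = c("absolute", "relative")) {
  loss <- match.arg(loss)
  data <- tibble::as_tibble(data)
  I <- if ("I_Wm2" %in% names(data)) data$I_Wm2 else
    microE_to_wm2(.pick_col(data, c("I_uE", "I"), "irradiance"))
  mu <- .pick_col(data, c("mu_h", "mu"), "growth-rate")
  if (length(unique(I)) < 4) {
    abort("Need at least 4 distinct irradiance levels to fit three constants.")
  }

  flags <- character(0)
  med <- tapply(mu, I, mean)
  peak <- which.max(med)
  if (peak == 1 || peak == length(med)) {
    warn("Observed growth rates are monotone in irradiance; the inhibition constant is weakly identified.")
    flags <- c(flags, "no_interior_maximum")
  }

  resid_fun <- function(theta) {
    p <- exp(theta)
    pred <- p[1] * I / (p[2] + I + I^2 / p[3])
    if (loss == "absolute") pred - mu else (pred - mu) / pmax(mu, 1e-6)
  }

  set.seed(seed)
  starts <- cbind(
    runif(n_starts, log(bounds$mu_max[1]), log(bounds$mu_max[2])),
    runif(n_starts, log(bounds$K[1]), log(bounds$K[2])),
    runif(n_starts, log(bounds$K[1]), log(bounds$K[2]))
  )
  # include a data-driven start: mu_max ~ max(mu), K at the peak intensity
  starts[1, ] <- log(c(max(max(mu), bounds$mu_max[1]),
                       max(I[which.max(mu)], bounds$K[1]),
                       max(I[which.max(mu)], bounds$K[1])))

  best <- NULL
  for (r in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[r, ], fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("All optimisation starts failed.")
  p <- exp(best$fit$par)
  converged <- best$fit$info %in% 1:4
  if (p[3] > 10 * max(bounds$K)) flags <- c(flags, "K_I_i_at_bound")

  est <- tibble::tibble(
    term = c("mu_max", "K_I_S", "K_I_i"),
    estimate = c(p[1], p[2], p[3]),
    unit = c("h^-1", "W m^-2", "W m^-2")
  )
  .new_fit("haldane", est, best$rss, converged, n_starts, seed,
           tibble::tibble(I_Wm2 = I, mu_h = mu), flags)
}

#' Fit the biomass absorption power law from transmission data
#'
#' Inverts each transmitted fraction to an absorption coefficient through
#' the scatter-free path law `kappa = -ln(T / T_abiotic) / L` (abiotic
#' losses removed multiplicatively) and fits `kappa = a X^b` by least
#' squares in log-log space.
#'
#' @param data Data frame with biomass (`X_gL` or `X`, gDCW/L) and
#'   transmitted-fraction (`T_frac` or `transmitted`) columns.
#' @param L Optical path length through the culture (m).
#' @param abiotic_transmission Transmitted fraction of the cell-free
#'   system, used to remove abiotic losses.
#' @return A `pbr_fit` with terms `a` and `b`.
#' @export
fit_absorption_law <- function(data, L = reactor_geometry()$thickness,
                               abiotic_transmission = 1) {
  data <- tibble::as_tibble(data)
  X <- .pick_col(data, c("X_gL", "X"), "biomass")
  Tf <- .pick_col(data, c("T_frac", "transmitted"), "transmitted-fraction")
  if (any(Tf <= 0) || any(Tf > 1)) {
    abort("Transmitted fractions must lie in (0, 1].")
  }
  if (any(X < 0)) abort("Biomass values must be >= 0.")
  keep <- X > 0
  if (length(unique(X[keep])) < 2) {
    abort("The exponent is unidentifiable: need at least 2 distinct positive biomass levels.")
  }
  if (length(unique(X)) < 3) {
    abort("Need at least 3 distinct biomass levels.")
  }
  kappa <- -log(Tf[keep] / abiotic_transmission) / L
  if (any(kappa <= 0)) {
    abort("Corrected transmissions imply non-positive absorption; check `abiotic_transmission`.")
  }
  fit <- lm(log(kappa) ~ log(X[keep]))
  a <- exp(unname(coef(fit)[1])); b <- unname(coef(fit)[2])
  est <- tibble::tibble(term = c("a", "b"),
                        estimate = c(a, b),
                        unit = c("m^-1 (gDCW/L)^-b", "1"))
  .new_fit("absorption_law", est, sum(fit$residuals^2), TRUE, 1L, NA_integer_,
           tibble::tibble(X_gL = X[keep], kappa = kappa))
}

#' Fit LED calibration factors from abiotic outlet data
#'
#' For each calibration case, regresses the measured outlet intensity
#' through the origin on the outlet intensity modelled with a unit
#' calibration factor; the slope is the case's multiplicative factor.
#'
#' @param data Data frame with columns `setpoint_uE` (or `setpoint`),
#'   `case`, and `I_out_uE` (or `I_out`).
#' @param geom,optics Geometry and abiotic optics used by the forward
#'   outlet model.
#' @param predict_fun Optional override: `function(setpoint_uE, case)`
#'   returning the modelled outlet intensity (uE) at unit calibration
#'   factor.
#' @return A `pbr_fit` with one `c_<case>` term per case present.
#' @export
fit_calibration_factors <- function(data, geom = reactor_geometry(),
                                    optics = optical_properties(),
                                    predict_fun = NULL) {
  data <- tibble::as_tibble(data)
  sp <- .pick_col(data, c("setpoint_uE", "setpoint"), "setpoint")
  Iout <- .pick_col(data, c("I_out_uE", "I_out"), "outlet-intensity")
  if (!"case" %in% names(data)) abort("Input table needs a `case` column.")
  cases <- sort(unique(data$case))
  if (length(cases) == 1) {
    warn("Only one calibration case present; returning a partial result.")
  }
  predict_fun <- predict_fun %||% function(setpoint_uE, case) {
    vapply(setpoint_uE, function(s) {
      panel_light_1d(geom, optics,
                     light_source(s, case, calibration_factor = 1))$I_out_uE
    }, numeric(1))
  }
  rows <- purrr::map_dfr(cases, function(cs) {
    sel <- data$case == cs
    if (length(unique(sp[sel])) < 2) {
      abort(sprintf("Need >= 2 setpoints for case %s.", cs))
    }
    m <- predict_fun(sp[sel], cs)
    ck <- sum(m * Iout[sel]) / sum(m^2) # origin regression slope
    tibble::tibble(term = paste0("c_", cs), estimate = ck, unit = "1",
                   rss = sum((Iout[sel] - ck * m)^2))
  })
  est <- rows[c("term", "estimate", "unit")]
  .new_fit("calibration_factors", est, sum(rows$rss), TRUE, 1L, NA_integer_,
           data,
           flags = if (length(cases) == 1) "single_case" else character(0))
}
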