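# ggplot2 visualisations for each result type.

#' @method autoplot pbr_two_flux
#' @export
autoplot.pbr_two_flux <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$y, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth y (m)", y = expression(G ~ (W ~ m^-2)),
                  title = "Two-flux irradiance profile")
}

#' @method autoplot pbr_panel_light
#' @export
autoplot.pbr_panel_light <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$y, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, max(object$profile$y)),
                        linetype = "dotted") +
    ggplot2::labs(x = "depth from inner front glass face (m)",
                  y = expression(G ~ (W ~ m^-2)),
                  title = sprintf("Panel light profile, %g uE (case %d)",
                                  object$source$setpoint,
                                  object$source$calibration_case))
}

#' @method autoplot pbr_light_field
#' @export
autoplot.pbr_light_field <- function(object, x_slice = NULL, ...) {
  xs <- object$axes$x
  xi <- if (is.null(x_slice)) which.min(abs(xs - stats::median(xs))) else
    which.min(abs(xs - x_slice))
  df <- expand.grid(y = object$axes$y, z = object$axes$z)
  df$G <- as.numeric(object$G[xi, , ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z,
                                   fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(G ~ (W ~ m^-2))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "depth y (m)", y = "height z (m)",
                  title = sprintf("Irradiance, y-z slice at x = %.3f m",
                                  xs[xi]))
}

#' @method autoplot pbr_simulation
#' @export
autoplot.pbr_simulation <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$results[c("setpoint_uE", "mu_obs_h", "dO2")],
    cols = c("mu_obs_h", "dO2"), names_to = "trait")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setpoint_uE,
                                   y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(mu_obs_h = "growth rate (1/h)",
                            dO2 = "dissolved O2 (% air sat.)"))) +
    ggplot2::labs(x = "light setpoint (uE)", y = NULL,
                  title = "Staircase response")
}

#' @method autoplot pbr_fit
#' @export
autoplot.pbr_fit <- function(object, ...) {
  if (object$model != "haldane") {
    abort("autoplot is implemented for Haldane fits; use tidy() otherwise.")
  }
  p <- setNames(object$estimates$estimate, object$estimates$term)
  kin <- kinetic_params(p[["mu_max"]], p[["K_I_S"]], p[["K_I_i"]])
  grid <- tibble::tibble(I_Wm2 = seq(0, max(object$data$I_Wm2) * 1.05,
                                     length.out = 200))
  grid$mu_h <- growth_rate(grid$I_Wm2, kin)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$I_Wm2,
                                            y = .data$mu_h)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = expression(I ~ (W ~ m^-2)),
                  y = expression(mu ~ (h^-1)),
                  title = "Haldane photo-growth fit")
}

#' @method autoplot pbr_light_history
#' @export
autoplot.pbr_light_history <- function(object, ...) {
  ens <- object |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(I_p = mean(.data$I_p), I_ab = mean(.data$I_ab),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("I_p", "I_ab"), names_to = "quantity")
  ggplot2::ggplot(ens, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(W ~ m^-2),
                  colour = NULL,
                  title = "Ensemble-mean perceived and absorbed light")
}

#' Bar chart of the per-domain light budget
#'
#' @param field A `pbr_light_field` or `pbr_panel_light`.
#' @return A ggplot object.
#' @export
plot_light_budget <- function(field) {
  df <- domain_light_budget(field)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$component,
                                                      -.data$fraction),
                                   y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of incident light",
                  title = "Light budget")
}

#' Efficiency versus setpoint for a simulated staircase
#'
#' @param sim A `pbr_simulation`.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(sim) {
  eff <- efficiency_table(sim)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$setpoint_uE,
                                    y = .data$efficiency_g_mol,
                                    colour = .data$variant)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "light setpoint (uE)",
                  y = "photosynthetic efficiency (gDCW / mol photons)",
                  colour = NULL)
}
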