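#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a scattering curve
#'
#' Log-log intensity versus q with uncertainty ribbon.
#'
#' @param object A `scattering_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scattering_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$intensity - .data$sigma,
                                                  .Machine$double.xmin),
                                      ymax = .data$intensity + .data$sigma),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = "I(q) (arb. units)") +
    ggplot2::theme_minimal()
}

#' Plot a SAXS fit
#'
#' Data with the fitted model overlaid (log-log).
#'
#' @param object A `saxs_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  dat <- tibble::as_tibble(object$data)
  dat$fitted <- object$fitted
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = "I(q) (arb. units)",
                  subtitle = sprintf("d_B = %.1f Å, N_UV = %.0f%%, chi2_red = %.2f",
                                     object$d_B, object$n_uv_percent,
                                     object$chi2_reduced)) +
    ggplot2::theme_minimal()
}

#' Plot the electron-density profile of a fitted or constructed model
#'
#' @param model A `bilayer_model`.
#' @param z_grid Positions across the bilayer, Angstrom.
#' @return A ggplot of the transverse contrast profile.
#' @export
plot_electron_density <- function(model, z_grid = seq(-40, 40, by = 0.1)) {
  prof <- electron_density_profile(model, z_grid)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(z ~ (ring(A))),
                  y = expression(rho(z) ~ "(rel. contrast)")) +
    ggplot2::theme_minimal()
}

#' Plot a thermogram
#'
#' @param object A `thermogram`.
#' @param ... Unused.
#' @return A ggplot of Cp versus temperature (degrees Celsius on the axis).
#' @export
autoplot.thermogram <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$temperature - 273.15,
                                    y = .data$cp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(C[p] ~ (kcal ~ mol^-1 ~ K^-1))) +
    ggplot2::theme_minimal()
}

#' Plot a GP image
#'
#' @param object A `gp_image`.
#' @param ... Unused.
#' @return A ggplot raster of the GP map (invalid pixels blank).
#' @export
autoplot.gp_image <- function(object, ...) {
  dat <- tibble::tibble(
    x = as.vector(col(object$gp)),
    y = as.vector(row(object$gp)),
    gp = as.vector(object$gp)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$gp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10", limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "GP") +
    ggplot2::theme_void()
}

#' Plot per-phase GP time series
#'
#' @param ts A tibble from [gp_timeseries()].
#' @return A ggplot of mean GP versus time for the l_o, l_d and whole-ring
#'   regions, with SD error bars.
#' @export
plot_gp_timeseries <- function(ts) {
  long <- tidyr::pivot_longer(
    ts, cols = tidyr::starts_with("gp_"),
    names_to = c("region", ".value"),
    names_pattern = "gp_(lo|ld|whole)_(mean|sd)"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mean,
                                     colour = .data$region)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.1, alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "Laurdan GP", colour = "Region") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
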