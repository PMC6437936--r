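#' Bilayer scattering model parameters
#'
#' Parameter set of the vesicle-suspension scattering model: a symmetric
#' three-Gaussian transverse electron-density contrast profile (two headgroup
#' Gaussians of unit amplitude at +/- `z_H`, one chain-region Gaussian of
#' relative amplitude `rho_C`, normally negative, at the bilayer center)
#' stacked into a lamellar lattice with modified Caille positional disorder,
#' mixed with a positionally non-correlated (unilamellar) population.
#'
#' @param z_H Headgroup Gaussian position from the bilayer center, Angstrom.
#' @param sigma_H Headgroup Gaussian width, Angstrom.
#' @param rho_C Chain-region amplitude relative to the headgroup amplitude,
#'   dimensionless (expected negative: CH2/CH3 region is electron-poor
#'   relative to water).
#' @param sigma_C Chain Gaussian width, Angstrom.
#' @param d Lamellar repeat distance (d-spacing), Angstrom.
#' @param N_layers Mean number of positionally correlated bilayers per stack,
#'   integer >= 1.
#' @param eta Caille bending-fluctuation parameter, dimensionless >= 0.
#' @param N_UV Fraction of positionally non-correlated (unilamellar)
#'   scatterers, in [0, 1].
#' @param scale Global intensity scale, > 0 (measured intensities are in
#'   arbitrary units).
#' @param background Additive constant background, >= 0.
#' @return A `bilayer_model` (a named list).
#' @examples
#' m <- bilayer_model(z_H = 20.1, sigma_H = 2.5, d = 65.8, N_UV = 0.52)
#' bilayer_thickness(m$z_H, m$sigma_H)
#' @export
bilayer_model <- function(z_H = 20, sigma_H = 3, rho_C = -1, sigma_C = 4,
                          d = 65, N_layers = 5L, eta = 0.1, N_UV = 0.5,
                          scale = 1, background = 0) {
  m <- list(z_H = z_H, sigma_H = sigma_H, rho_C = rho_C, sigma_C = sigma_C,
            d = d, N_layers = as.integer(round(N_layers)), eta = eta,
            N_UV = N_UV, scale = scale, background = background)
  validate_bilayer_model(m)
  structure(m, class = "bilayer_model")
}

validate_bilayer_model <- function(m) {
  with(m, {
    if (z_H <= 0) stop("z_H must be > 0", call. = FALSE)
    if (sigma_H <= 0) stop("sigma_H must be > 0", call. = FALSE)
    if (sigma_C <= 0) stop("sigma_C must be > 0", call. = FALSE)
    if (N_UV < 0 || N_UV > 1) stop("N_UV must lie in [0, 1]", call. = FALSE)
    if (N_layers < 1L) stop("N_layers must be >= 1", call. = FALSE)
    if (eta < 0) stop("eta must be >= 0", call. = FALSE)
    if (d <= 2 * z_H) stop("d must exceed 2*z_H (bilayers cannot interpenetrate)",
                           call. = FALSE)
    if (scale <= 0) stop("scale must be > 0", call. = FALSE)
    if (background < 0) stop("background must be >= 0", call. = FALSE)
  })
  invisible(m)
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("<bilayer_model>\n")
  cat(sprintf("  headgroup: z_H = %.3g A, sigma_H = %.3g A\n", x$z_H, x$sigma_H))
  cat(sprintf("  chains:    rho_C = %.3g, sigma_C = %.3g A\n", x$rho_C, x$sigma_C))
  cat(sprintf("  stack:     d = %.4g A, N_layers = %d, eta = %.3g\n",
              x$d, x$N_layers, x$eta))
  cat(sprintf("  mixture:   N_UV = %.3g, scale = %.3g, background = %.3g\n",
              x$N_UV, x$scale, x$background))
  cat(sprintf("  derived:   d_B = %.4g A\n", bilayer_thickness(x$z_H, x$sigma_H)))
  invisible(x)
}

#' Bilayer form factor
#'
#' Analytic Fourier transform of the symmetric three-Gaussian electron-density
#' contrast profile:
#' \deqn{F(q) = \sqrt{2\pi}\,[\,2\sigma_H e^{-\sigma_H^2 q^2/2}\cos(q z_H)
#'   + \rho_C \sigma_C e^{-\sigma_C^2 q^2/2}\,].}
#' Even in q; carries the sign of the amplitude (it is squared in the
#' intensity model).
#'
#' @param q Scattering vector, A^-1 (any numeric vector).
#' @param model A `bilayer_model`.
#' @return Form-factor amplitude at each q, arbitrary units.
#' @export
form_factor <- function(q, model) {
  sqrt(2 * pi) * (
    2 * model$sigma_H * exp(-model$sigma_H^2 * q^2 / 2) * cos(q * model$z_H) +
      model$rho_C * model$sigma_C * exp(-model$sigma_C^2 * q^2 / 2)
  )
}

#' Modified Caille lamellar structure factor
#'
#' Inter-bilayer correlation term for a stack of `N_layers` bilayers with
#' repeat `d` and bending-fluctuation (Caille) parameter `eta`:
#' \deqn{S(q) = N + 2\sum_{k=1}^{N-1}(N-k)\cos(kqd)\,
#'   e^{-(d/2\pi)^2 q^2 \eta\, \gamma_E}\,(\pi k)^{-(d/2\pi)^2 q^2 \eta}}
#' with Euler-Mascheroni constant \eqn{\gamma_E = 0.5772157}. The truncated
#' sum can ring slightly negative; it is floored at 0 here because S(q) enters
#' the intensity as a weight.
#'
#' @inheritParams form_factor
#' @return S(q) >= 0, dimensionless; identically 1 when `N_layers = 1`.
#' @export
structure_factor <- function(q, model) {
  N <- model$N_layers
  if (N == 1L) return(rep(1, length(q)))
  euler_gamma <- 0.5772156649015329
  alpha <- (model$d / (2 * pi))^2 * q^2 * model$eta  # per-q Caille exponent
  k <- seq_len(N - 1L)
  # terms: outer over q x k
  cosqd <- cos(outer(q * model$d, k))
  damp <- exp(-alpha * euler_gamma) * exp(-outer(alpha, log(pi * k)))
  s <- N + 2 * as.vector((cosqd * damp) %*% (N - k))
  pmax(s, 0)
}

#' Model scattering intensity of a vesicle suspension
#'
#' Mixture of positionally correlated (multilamellar) and non-correlated
#' (unilamellar) bilayers:
#' \deqn{I(q) = s\,[\,(1-N_{UV})\,S(q)\,|F(q)|^2/q^2
#'   + N_{UV}\,|F(q)|^2/q^2\,] + b.}
#' The \eqn{1/q^2} Lorentz factor reflects the powder average over randomly
#' oriented planar scatterers.
#'
#' @inheritParams form_factor
#' @return Model intensity at each q.
#' @export
model_intensity <- function(q, model) {
  if (any(q <= 0)) stop("q must be > 0 (1/q^2 singularity at q = 0)", call. = FALSE)
  F2q2 <- form_factor(q, model)^2 / q^2
  S <- structure_factor(q, model)
  model$scale * ((1 - model$N_UV) * S * F2q2 + model$N_UV * F2q2) + model$background
}

#' Membrane thickness from headgroup parameters
#'
#' \deqn{d_B = 2(z_H + 2\sigma_H)}: the bilayer spans the headgroup peaks plus
#' two Gaussian widths on each side.
#'
#' @param z_H Headgroup position from the bilayer center, Angstrom, >= 0.
#' @param sigma_H Headgroup Gaussian width, Angstrom, >= 0.
#' @return Membrane thickness d_B in Angstrom.
#' @examples
#' bilayer_thickness(20.1, 2.5)  # 50.2
#' @export
bilayer_thickness <- function(z_H, sigma_H) {
  if (any(z_H < 0) || any(sigma_H < 0)) {
    stop("z_H and sigma_H must be non-negative", call. = FALSE)
  }
  2 * (z_H + 2 * sigma_H)
}

#' Transverse electron-density contrast profile
#'
#' The real-space profile whose Fourier transform is [form_factor()]:
#' \deqn{\rho(z) = e^{-(z-z_H)^2/2\sigma_H^2} + e^{-(z+z_H)^2/2\sigma_H^2}
#'   + \rho_C e^{-z^2/2\sigma_C^2}.}
#'
#' @param model A `bilayer_model`.
#' @param z_grid Positions across the bilayer, Angstrom (conventionally
#'   symmetric about 0).
#' @return A tibble with columns `z` and `rho` for plotting.
#' @export
electron_density_profile <- function(model, z_grid = seq(-40, 40, by = 0.1)) {
  rho <- exp(-(z_grid - model$z_H)^2 / (2 * model$sigma_H^2)) +
    exp(-(z_grid + model$z_H)^2 / (2 * model$sigma_H^2)) +
    model$rho_C * exp(-z_grid^2 / (2 * model$sigma_C^2))
  tibble::tibble(z = z_grid, rho = rho)
}

#' Quasi-Bragg peak positions of a lamellar stack
#'
#' @param d Lamellar repeat distance, Angstrom, > 0.
#' @param orders Integer diffraction orders, all >= 1.
#' @return q positions `orders * 2*pi/d` in A^-1.
#' @examples
#' bragg_positions(65.8, 1:2)  # ~0.0955 and ~0.1910 A^-1
#' @export
bragg_positions <- function(d, orders = 1:4) {
  if (d <= 0) stop("d must be > 0", call. = FALSE)
  orders <- as.integer(orders)
  if (any(orders < 1L)) stop("diffraction orders must be positive integers", call. = FALSE)
  orders * 2 * pi / d
}
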