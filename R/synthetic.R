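# run code with a temporary RNG state so generators are seeded but do not
# clobber the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a SAXS curve of a vesicle suspension
#'
#' Forward-evaluates [model_intensity()] on a q grid and applies seeded
#' multiplicative Gaussian noise: `I = I_model * (1 + e)`,
#' `e ~ N(0, noise_fraction)`, with `sigma = noise_fraction * I_model` —
#' the roughly constant relative uncertainty typical of a long
#' background-subtracted acquisition. With `noise_fraction = 0` the intensity
#' is the exact model curve and a nominal `sigma = 0.01 * I_model` is
#' attached so that weighted fitting remains defined.
#'
#' @param truth A `bilayer_model`: the generating ground truth.
#' @param q_grid Scattering vector grid, A^-1, positive and increasing. The
#'   default spans 0.015-0.447 A^-1, a typical laboratory-source window
#'   around the first two lamellar diffraction orders.
#' @param noise_fraction Relative noise level (0.01 = 1%).
#' @param seed Integer seed.
#' @return A `saxs_simulation`: list with `curve` (a `scattering_curve`) and
#'   `ground_truth` (the generating model plus seed and noise level).
#' @examples
#' sim <- simulate_saxs_curve(saxs_preset("saxs_control"), seed = 1)
#' head(sim$curve)
#' @export
simulate_saxs_curve <- function(truth,
                                q_grid = seq(0.015, 0.447, length.out = 300),
                                noise_fraction = 0.01,
                                seed = 1L) {
  validate_bilayer_model(truth)
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0)) {
    stop("q_grid must be positive and increasing", call. = FALSE)
  }
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  I_model <- model_intensity(q_grid, truth)
  if (noise_fraction > 0) {
    eps <- with_seed(seed, stats::rnorm(length(q_grid), 0, noise_fraction))
    intensity <- I_model * (1 + eps)
    sigma <- noise_fraction * I_model
  } else {
    intensity <- I_model
    sigma <- 0.01 * I_model  # nominal weights; intensity itself is exact
  }
  structure(
    list(
      curve = new_scattering_curve(q_grid, intensity, sigma),
      ground_truth = list(model = unclass(truth), seed = as.integer(seed),
                          noise_fraction = noise_fraction)
    ),
    class = "saxs_simulation"
  )
}

#' Simulate a two-state DSC endotherm
#'
#' Exact two-state (all-or-none) excess heat capacity: with equilibrium
#' constant \eqn{K(T) = \exp[-(\Delta H_{VH}/R)(1/T - 1/T_m)]},
#' \deqn{C_p(T) = \Delta H_{cal}\,\frac{\Delta H_{VH}}{R T^2}
#'   \frac{K}{(1+K)^2},}
#' plus a linear instrumental baseline `baseline_slope * T` and seeded
#' additive Gaussian noise. The curve integrates exactly to `dH_cal`; its
#' FWHM is \eqn{3.5255\,R T_m^2/\Delta H_{VH}} (half-maximum at
#' \eqn{K = 3 \pm 2\sqrt 2}), which is why the factor-4 estimator of
#' [vant_hoff_enthalpy()] over-reports a true two-state enthalpy by
#' 4/3.5255.
#'
#' @param Tm Transition temperature, K.
#' @param dH_cal Calorimetric enthalpy, kcal/mol.
#' @param dH_vH_true True (two-state) van't Hoff enthalpy, kcal/mol.
#' @param T_grid Temperature grid, K; must cover `Tm` plus/minus 2 FWHM.
#' @param baseline_slope Linear baseline slope, kcal mol^-1 K^-2.
#' @param noise_sd Additive Gaussian noise SD, kcal mol^-1 K^-1.
#' @param seed Integer seed.
#' @param R Gas constant, cal mol^-1 K^-1.
#' @return A `dsc_simulation`: list with `thermogram` and `ground_truth`.
#' @examples
#' sim <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8)
#' @export
simulate_thermogram <- function(Tm, dH_cal, dH_vH_true,
                                T_grid = seq(278.15, 328.15, by = 0.01),
                                baseline_slope = 0,
                                noise_sd = 0,
                                seed = 1L,
                                R = 1.9872) {
  if (any(diff(T_grid) <= 0)) stop("T_grid must be increasing", call. = FALSE)
  fwhm <- 3.5255 * R * Tm^2 / (dH_vH_true * 1000)
  # +/- 2 FWHM leaves < 0.2% of the transition enthalpy outside the grid;
  # widen the grid further when integrals must close tighter than that
  if (min(T_grid) > Tm - 2 * fwhm || max(T_grid) < Tm + 2 * fwhm) {
    stop("T_grid too narrow: must cover Tm +/- 2 FWHM (",
         format(2 * fwhm, digits = 3), " K)", call. = FALSE)
  }
  dH_vH_cal <- dH_vH_true * 1000
  K <- exp(-(dH_vH_cal / R) * (1 / T_grid - 1 / Tm))
  cp <- dH_cal * dH_vH_cal / (R * T_grid^2) * K / (1 + K)^2
  cp <- cp + baseline_slope * T_grid
  if (noise_sd > 0) {
    cp <- cp + with_seed(seed, stats::rnorm(length(T_grid), 0, noise_sd))
  }
  structure(
    list(
      thermogram = new_thermogram(T_grid, cp, scan_rate = 0.5,
                                  baseline_subtracted = FALSE),
      ground_truth = list(Tm = Tm, dH_cal = dH_cal, dH_vH_true = dH_vH_true,
                          fwhm_true = fwhm, baseline_slope = baseline_slope,
                          noise_sd = noise_sd, seed = as.integer(seed))
    ),
    class = "dsc_simulation"
  )
}

#' Simulate an equatorial GUV image sequence with coexisting phases
#'
#' Builds two-channel frames of a single vesicle ring on a dark background.
#' The ring of radius `radius_px` carries a liquid-ordered arc (GP `gp_lo`)
#' covering `arc_fraction_lo` of the circumference, the remainder
#' liquid-disordered (GP `gp_ld`). Channels are constructed by inverting the
#' GP definition at total intensity S: `I440 = S*(1+GP)/2`,
#' `I490 = S*(1-GP)/(2*g_factor)`, then Poisson noise is applied per channel.
#' From `step_frame` onward both phase GPs increase by `step_delta_gp`,
#' emulating an interfacial dehydration event such as the addition of a
#' membrane-active compound.
#'
#' @param radius_px Ring radius, pixels.
#' @param arc_fraction_lo Fraction of the circumference occupied by the
#'   liquid-ordered arc, in [0, 1].
#' @param gp_lo,gp_ld Ground-truth GP of the two phases, each in (-1, 1).
#' @param mean_counts Mean total intensity (both channels, counts) on the
#'   ring.
#' @param g_factor Instrument G factor baked into the red channel.
#' @param image_size_px Square frame side, pixels.
#' @param ring_width_px Full radial width of the ring, pixels.
#' @param background_counts Mean background level per channel, counts.
#' @param n_frames Number of time points (1 frame per minute).
#' @param step_frame 1-based frame index at which the GP step occurs
#'   (`NULL` or > `n_frames` for no step).
#' @param step_delta_gp GP increase applied to both phases from `step_frame`
#'   onward.
#' @param poisson_noise If `FALSE`, channels carry their exact Poisson means
#'   (noiseless frames, exactly invertible by [compute_gp_image()]).
#' @param seed Integer seed.
#' @return A `guv_simulation`: list with `frames` (list of
#'   `two_channel_image`) and `ground_truth`.
#' @examples
#' sim <- simulate_guv_frames(n_frames = 2, image_size_px = 64,
#'                            radius_px = 20, seed = 7)
#' @export
simulate_guv_frames <- function(radius_px = 40,
                                arc_fraction_lo = 1 / 3,
                                gp_lo = 0.45,
                                gp_ld = 0.05,
                                mean_counts = 500,
                                g_factor = 1,
                                image_size_px = 128,
                                ring_width_px = 6,
                                background_counts = 1,
                                n_frames = 5,
                                step_frame = 3,
                                step_delta_gp = 0.05,
                                poisson_noise = TRUE,
                                seed = 7L) {
  if (radius_px + ring_width_px >= image_size_px / 2) {
    stop("ring does not fit: radius + ring width must be < image_size/2",
         call. = FALSE)
  }
  gp_max <- max(abs(c(gp_lo, gp_ld,
                      gp_lo + step_delta_gp, gp_ld + step_delta_gp)))
  if (gp_max >= 1) stop("|GP| must stay below 1 everywhere", call. = FALSE)

  n <- image_size_px
  cx <- (n + 1) / 2
  rr <- sqrt((row(matrix(0, n, n)) - cx)^2 + (col(matrix(0, n, n)) - cx)^2)
  on_ring <- abs(rr - radius_px) <= ring_width_px / 2
  theta <- atan2(col(matrix(0, n, n)) - cx, row(matrix(0, n, n)) - cx) %% (2 * pi)
  lo_arc <- on_ring & theta < 2 * pi * arc_fraction_lo

  frames <- with_seed(seed, {
    purrr::map(seq_len(n_frames), function(fr) {
      delta <- if (!is.null(step_frame) && fr >= step_frame) step_delta_gp else 0
      gp <- matrix(0, n, n)
      gp[on_ring] <- gp_ld + delta
      gp[lo_arc] <- gp_lo + delta
      S <- matrix(2 * background_counts, n, n)
      S[on_ring] <- mean_counts
      lam440 <- S * (1 + gp) / 2
      lam490 <- S * (1 - gp) / (2 * g_factor)
      if (poisson_noise) {
        new_two_channel_image(
          I440 = matrix(stats::rpois(n * n, lam440), n, n),
          I490 = matrix(stats::rpois(n * n, lam490), n, n),
          timestamp = fr - 1
        )
      } else {
        new_two_channel_image(I440 = lam440, I490 = lam490, timestamp = fr - 1)
      }
    })
  })

  structure(
    list(
      frames = frames,
      ground_truth = list(
        radius_px = radius_px, arc_fraction_lo = arc_fraction_lo,
        gp_lo = gp_lo, gp_ld = gp_ld, mean_counts = mean_counts,
        g_factor = g_factor, image_size_px = image_size_px,
        ring_width_px = ring_width_px, background_counts = background_counts,
        n_frames = n_frames, step_frame = step_frame,
        step_delta_gp = step_delta_gp, seed = as.integer(seed)
      )
    ),
    class = "guv_simulation"
  )
}

#' Preset ground-truth parameter sets
#'
#' Named regimes matching the experimental conditions the generators emulate:
#' an extruded DOPC/DPPC/cholesterol 23:47:30 suspension without
#' (`saxs_control`) and with 10 mol% artepillin C (`saxs_artepillin`); the
#' corresponding broad DSC endotherms at 0, 5 and 10 mol% (`dsc_control`,
#' `dsc_artepillin5`, `dsc_artepillin10`); and a phase-separated GUV
#' time series (`guv_default`).
#'
#' For the DSC presets the stated true van't Hoff enthalpies are those whose
#' factor-4 width estimate (see [vant_hoff_enthalpy()]) reproduces the
#' conventionally reported values 75.8, 54.1 and 41.2 kcal/mol.
#'
#' @param name Preset name.
#' @return For `saxs_preset`, a `bilayer_model`; for `dsc_preset` and
#'   `guv_preset`, a named list of generator arguments.
#' @examples
#' saxs_preset("saxs_control")
#' dsc_preset("dsc_control")
#' @export
saxs_preset <- function(name = c("saxs_control", "saxs_artepillin")) {
  name <- match.arg(name)
  switch(name,
    saxs_control = bilayer_model(
      z_H = 20.1, sigma_H = 2.5, rho_C = -1.2, sigma_C = 4,
      d = 65.8, N_layers = 5L, eta = 0.1, N_UV = 0.52,
      scale = 1, background = 1e-3
    ),
    saxs_artepillin = bilayer_model(
      z_H = 19.6, sigma_H = 2.2, rho_C = -1.2, sigma_C = 4,
      d = 71.4, N_layers = 5L, eta = 0.1, N_UV = 0.87,
      scale = 1, background = 1e-3
    )
  )
}

#' @rdname saxs_preset
#' @export
dsc_preset <- function(name = c("dsc_control", "dsc_artepillin5",
                                "dsc_artepillin10")) {
  name <- match.arg(name)
  # dH_vH_true = reported-value / (4 / 3.5255)
  switch(name,
    dsc_control = list(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.81),
    dsc_artepillin5 = list(Tm = 308.05, dH_cal = 1.3, dH_vH_true = 47.68),
    dsc_artepillin10 = list(Tm = 309.65, dH_cal = 1.4, dH_vH_true = 36.31)
  )
}

#' @rdname saxs_preset
#' @export
guv_preset <- function(name = "guv_default") {
  name <- match.arg(name)
  list(radius_px = 40, arc_fraction_lo = 1 / 3, gp_lo = 0.45, gp_ld = 0.05,
       mean_counts = 500, g_factor = 1, image_size_px = 128,
       ring_width_px = 6, n_frames = 5, step_frame = 3, step_delta_gp = 0.05,
       seed = 7L)
}
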