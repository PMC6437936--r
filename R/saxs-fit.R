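#' Fit the vesicle-suspension scattering model to a measured curve
#'
#' Weighted least squares (weights `1/sigma^2`) of [model_intensity()] against
#' a measured curve. The continuous parameters (`z_H`, `sigma_H`, `rho_C`,
#' `sigma_C`, `d`, `eta`, `N_UV`, `scale`, `background`) are optimized by
#' bounded Levenberg-Marquardt; the integer stack size `N_layers` is fitted by
#' an exhaustive loop. Because the quasi-Bragg region creates many local
#' minima in `d` and the diffuse/lamellar mixture in `N_UV`, each `N_layers`
#' is multi-started over a grid of `d` and `N_UV` initial values; the best
#' solution by reduced chi-squared wins, ties broken by the smaller
#' `N_layers`.
#'
#' @param curve A `scattering_curve` (see [read_scattering_curve()] or
#'   [simulate_saxs_curve()]) with at least 50 points spanning a decade in q.
#' @param init A `bilayer_model` giving initial values for the parameters not
#'   covered by the multi-start grid.
#' @param lower,upper Named numeric vectors of box bounds for the continuous
#'   parameters; entries you supply override the defaults.
#' @param n_layers_range Integer candidates for `N_layers`.
#' @param d_starts,nuv_starts Multi-start grid over the lamellar repeat
#'   (Angstrom) and the unilamellar fraction.
#' @param q_min,q_max Optional fitting window in A^-1 (beam-stop contamination
#'   at low q is common); default is the full curve.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A `saxs_fit` with elements `model` (the fitted `bilayer_model`),
#'   `uncertainties` (per-parameter standard errors from the local quadratic
#'   approximation), `chi2_reduced`, `d_B` and `d_B_se` (Angstrom),
#'   `n_uv_percent`, `at_bounds` (names of parameters that finished on a
#'   bound, if any), and the fitted curve for plotting.
#' @examples
#' truth <- bilayer_model(z_H = 20.1, sigma_H = 2.5, rho_C = -1.2, sigma_C = 4,
#'                        d = 65.8, N_layers = 5, eta = 0.1, N_UV = 0.52,
#'                        scale = 1, background = 0.001)
#' sim <- simulate_saxs_curve(truth, noise_fraction = 0.01, seed = 1)
#' fit <- fit_curve(sim$curve, n_layers_range = 4:6)
#' glance(fit)
#' @export
fit_curve <- function(curve,
                      init = bilayer_model(),
                      lower = NULL, upper = NULL,
                      n_layers_range = 1:8,
                      d_starts = c(55, 60, 65, 70, 75, 80),
                      nuv_starts = c(0.3, 0.7),
                      q_min = NULL, q_max = NULL,
                      max_iter = 200L) {
  stopifnot(inherits(curve, "scattering_curve") || is.data.frame(curve))
  dat <- tibble::as_tibble(curve)[, c("q", "intensity", "sigma")]
  if (!is.null(q_min)) dat <- dat[dat$q >= q_min, ]
  if (!is.null(q_max)) dat <- dat[dat$q <= q_max, ]
  if (nrow(dat) < 50L) stop("need at least 50 points in the fitting window", call. = FALSE)
  if (max(dat$q) / min(dat$q) < 10) {
    stop("q-range must span at least one decade", call. = FALSE)
  }
  if (any(dat$sigma <= 0)) stop("all sigma must be > 0 for weighted fitting", call. = FALSE)

  par_names <- c("z_H", "sigma_H", "rho_C", "sigma_C", "d", "eta", "N_UV",
                 "scale", "background")
  lo <- c(z_H = 10, sigma_H = 1, rho_C = -3, sigma_C = 1.5, d = 45, eta = 0,
          N_UV = 0, scale = 1e-12, background = 0)
  hi <- c(z_H = 30, sigma_H = 6, rho_C = -0.05, sigma_C = 10, d = 95, eta = 1,
          N_UV = 1, scale = Inf, background = Inf)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  eval_model <- function(p, N) {
    m <- list(z_H = p[["z_H"]], sigma_H = p[["sigma_H"]], rho_C = p[["rho_C"]],
              sigma_C = p[["sigma_C"]], d = p[["d"]], N_layers = N,
              eta = p[["eta"]], N_UV = p[["N_UV"]], scale = p[["scale"]],
              background = p[["background"]])
    model_intensity(dat$q, m)
  }
  resid_fn <- function(p, N) (eval_model(p, N) - dat$intensity) / dat$sigma

  start_for <- function(d0, nuv0, N) {
    p <- c(z_H = init$z_H, sigma_H = init$sigma_H, rho_C = init$rho_C,
           sigma_C = init$sigma_C, d = d0, eta = init$eta, N_UV = nuv0,
           scale = 1, background = 0)
    p <- pmin(pmax(p, lo), hi)  # clamp into bounds
    # robust scale init: median data/model ratio (a weighted projection is
    # fragile when the Bragg peaks of the start model are misaligned)
    shape <- eval_model(p, N)
    p[["scale"]] <- max(stats::median(dat$intensity / shape), lo[["scale"]])
    p
  }

  # Levenberg-Marquardt with restarts: re-launching from the endpoint resets
  # the trust region and routinely escapes shallow stalls near ridges
  polish <- function(p0, N) {
    chi <- Inf
    fit <- NULL
    for (k in 1:4) {
      res <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                             fn = resid_fn, N = N,
                             control = minpack.lm::nls.lm.control(
                               maxiter = max_iter, maxfev = 20000L))),
        error = function(e) NULL
      )
      if (is.null(res)) break
      fit <- res
      p0 <- res$par
      if (res$deviance > 0.99 * chi) { chi <- min(chi, res$deviance); break }
      chi <- res$deviance
    }
    fit
  }

  n_free <- length(par_names)

  # refinement: the weighted-LS landscape has shallow secondary basins in
  # which the optimizer can settle with slightly biased (N_UV, scale);
  # deterministic single-parameter jitters of the profile-shape terms
  # reliably hop out of them. Run per N_layers candidate so that the
  # integer-N selection compares refined optima.
  refine <- function(cand, max_rounds = 3L) {
    for (round in seq_len(max_rounds)) {
      improved <- FALSE
      for (nm in c("sigma_H", "sigma_C", "rho_C", "eta", "N_UV")) {
        for (fac in c(0.8, 1.2)) {
          p_j <- cand$fit$par
          p_j[[nm]] <- min(max(p_j[[nm]] * fac, lo[[nm]] + 1e-9), hi[[nm]])
          res <- polish(p_j, cand$N)
          if (!is.null(res) &&
              res$deviance < cand$fit$deviance * (1 - 1e-3)) {
            cand$fit <- res
            cand$chi2_red <- res$deviance / (nrow(dat) - n_free)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    cand
  }

  best <- NULL
  diagnostics <- list()
  for (N in sort(unique(as.integer(n_layers_range)))) {
    cand <- NULL  # best across starts for this N
    grid <- expand.grid(d0 = d_starts, nuv0 = nuv_starts)
    for (g in seq_len(nrow(grid))) {
      p0 <- start_for(grid$d0[g], grid$nuv0[g], N)
      res <- polish(p0, N)
      if (is.null(res)) {
        diagnostics[[length(diagnostics) + 1L]] <-
          list(N_layers = N, start = p0, message = "optimizer error")
        next
      }
      chi2_red <- res$deviance / (nrow(dat) - n_free)
      if (is.null(cand) || chi2_red < cand$chi2_red) {
        cand <- list(fit = res, N = N, chi2_red = chi2_red)
      }
    }
    if (is.null(cand)) next
    cand <- refine(cand)
    better <- is.null(best) ||
      cand$chi2_red < best$chi2_red - 1e-12 ||
      (abs(cand$chi2_red - best$chi2_red) <= 1e-12 && cand$N < best$N)
    if (better) best <- cand
  }

  if (is.null(best)) {
    stop("SAXS fit failed to converge from any start; diagnostics: ",
         paste(vapply(diagnostics, function(d) {
           sprintf("N=%d: %s", d$N_layers, d$message)
         }, character(1)), collapse = "; "), call. = FALSE)
  }

  p <- best$fit$par
  model <- structure(
    list(z_H = p[["z_H"]], sigma_H = p[["sigma_H"]], rho_C = p[["rho_C"]],
         sigma_C = p[["sigma_C"]], d = p[["d"]], N_layers = best$N,
         eta = p[["eta"]], N_UV = p[["N_UV"]], scale = p[["scale"]],
         background = p[["background"]]),
    class = "bilayer_model"
  )

  # standard errors from the local quadratic approximation at the optimum
  se <- rep(NA_real_, n_free)
  names(se) <- par_names
  cov <- NULL
  hess <- try(best$fit$hessian, silent = TRUE)
  if (!inherits(hess, "try-error") && !is.null(hess)) {
    covm <- try(solve(hess) * 2 * best$chi2_red, silent = TRUE)
    if (!inherits(covm, "try-error") && all(is.finite(diag(covm))) &&
        all(diag(covm) >= 0)) {
      cov <- covm
      se <- sqrt(diag(covm))
      names(se) <- par_names
    }
  }

  tol_bound <- 1e-6
  at_lo <- par_names[abs(p - lo[par_names]) < tol_bound * pmax(1, abs(p))]
  at_hi <- par_names[is.finite(hi[par_names]) &
                       abs(p - hi[par_names]) < tol_bound * pmax(1, abs(p))]
  at_bounds <- union(at_lo, at_hi)
  if (length(at_bounds)) {
    warning("parameter(s) at a bound: ", paste(at_bounds, collapse = ", "),
            call. = FALSE)
  }

  d_B <- bilayer_thickness(model$z_H, model$sigma_H)
  d_B_se <- if (!is.null(cov)) {
    # d_B = 2 z_H + 4 sigma_H
    g <- c(2, 4)
    idx <- match(c("z_H", "sigma_H"), par_names)
    v <- as.numeric(t(g) %*% cov[idx, idx] %*% g)
    if (v >= 0) sqrt(v) else NA_real_
  } else NA_real_

  structure(
    list(
      model = model,
      uncertainties = se,
      chi2_reduced = best$chi2_red,
      d_B = d_B,
      d_B_se = d_B_se,
      n_uv_percent = 100 * model$N_UV,
      at_bounds = at_bounds,
      n_points = nrow(dat),
      data = new_scattering_curve(dat$q, dat$intensity, dat$sigma),
      fitted = model_intensity(dat$q, model)
    ),
    class = "saxs_fit"
  )
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat("<saxs_fit>  chi2_red =", format(x$chi2_reduced, digits = 4),
      " on", x$n_points, "points\n")
  cat(sprintf("  d_B   = %.2f +/- %.2f A\n", x$d_B,
              if (is.na(x$d_B_se)) NA else x$d_B_se))
  cat(sprintf("  N_UV  = %.1f %%\n", x$n_uv_percent))
  cat(sprintf("  d     = %.2f A, N_layers = %d, eta = %.3g\n",
              x$model$d, x$model$N_layers, x$model$eta))
  if (length(x$at_bounds)) {
    cat("  note: parameter(s) at bound:", paste(x$at_bounds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn fit_curve Tidy per-parameter summary of a `saxs_fit`.
#' @param x A `saxs_fit`.
#' @param ... Unused.
#' @export
tidy.saxs_fit <- function(x, ...) {
  par_names <- c("z_H", "sigma_H", "rho_C", "sigma_C", "d", "eta", "N_UV",
                 "scale", "background")
  est <- vapply(par_names, function(nm) x$model[[nm]], numeric(1))
  tibble::tibble(
    term = par_names,
    estimate = unname(est),
    std.error = unname(x$uncertainties[par_names]),
    at.bound = par_names %in% x$at_bounds
  )
}

#' @describeIn fit_curve One-row goodness-of-fit and derived-quantity summary.
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(
    chi2.reduced = x$chi2_reduced,
    d.B = x$d_B,
    d.B.se = x$d_B_se,
    n.uv.percent = x$n_uv_percent,
    d.spacing = x$model$d,
    n.layers = x$model$N_layers,
    nobs = x$n_points
  )
}
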