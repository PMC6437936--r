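#' Subtract a linear chord baseline from a thermogram
#'
#' A straight line through the two anchor points `(T_low, Cp(T_low))` and
#' `(T_high, Cp(T_high))` is subtracted; outside `[T_low, T_high]` the excess
#' heat capacity is set to 0. Anchor values are read off the scan by linear
#' interpolation so the anchors need not coincide with grid points.
#'
#' @param tg A `thermogram` (see [read_thermogram()] or
#'   [simulate_thermogram()]).
#' @param T_low,T_high Chord anchors in kelvin, bracketing the transition and
#'   inside the scan range.
#' @return A baseline-subtracted `thermogram`.
#' @export
subtract_baseline <- function(tg, T_low, T_high) {
  stopifnot(inherits(tg, "thermogram") || is.data.frame(tg))
  Tv <- tg$temperature
  if (T_low >= T_high) stop("T_low must be < T_high", call. = FALSE)
  if (T_low < min(Tv) || T_high > max(Tv)) {
    stop("baseline limits outside the scan range [", format(min(Tv)), ", ",
         format(max(Tv)), "] K", call. = FALSE)
  }
  cp_lo <- stats::approx(Tv, tg$cp, xout = T_low)$y
  cp_hi <- stats::approx(Tv, tg$cp, xout = T_high)$y
  slope <- (cp_hi - cp_lo) / (T_high - T_low)
  chord <- cp_lo + slope * (Tv - T_low)
  cp <- tg$cp - chord
  cp[Tv < T_low | Tv > T_high] <- 0
  new_thermogram(Tv, cp, scan_rate = attr(tg, "scan_rate"),
                 baseline_subtracted = TRUE)
}

#' Peak parameters of a single endotherm
#'
#' Extracts from a baseline-subtracted thermogram: the transition temperature
#' `Tm` (temperature of maximum excess heat capacity, refined by a parabola
#' through the three points around the discrete maximum), the full width at
#' half maximum `T_half` (each half-height crossing located by linear
#' interpolation), and the calorimetric enthalpy `dH_cal` (trapezoidal
#' integral of Cp over the window).
#'
#' @inheritParams subtract_baseline
#' @param T_low,T_high Integration window in kelvin containing a single
#'   dominant maximum.
#' @return A list with `Tm` (K), `T_half` (K) and `dH_cal` (kcal/mol).
#' @export
transition_parameters <- function(tg, T_low, T_high) {
  stopifnot(inherits(tg, "thermogram") || is.data.frame(tg))
  if (!isTRUE(attr(tg, "baseline_subtracted"))) {
    stop("thermogram is not baseline-subtracted; call subtract_baseline() first",
         call. = FALSE)
  }
  sel <- tg$temperature >= T_low & tg$temperature <= T_high
  Tv <- tg$temperature[sel]
  cp <- tg$cp[sel]
  if (length(Tv) < 5L) stop("too few points inside the window", call. = FALSE)

  i <- which.max(cp)
  Tm <- Tv[i]
  if (i > 1L && i < length(Tv)) {
    # parabolic refinement through the three points around the discrete max
    x <- Tv[(i - 1):(i + 1)]
    y <- cp[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) Tm <- -b / (2 * a)
  }

  half <- cp[i] / 2
  below_left <- which(cp[seq_len(i)] < half)
  below_right <- which(cp[seq(i, length(cp))] < half)
  if (!length(below_left) || !length(below_right)) {
    stop("peak truncated: half-maximum not crossed on both sides inside the window",
         call. = FALSE)
  }
  # linear interpolation of the half crossing between samples j and j+1
  cross_at <- function(j) {
    Tv[j] + (half - cp[j]) / (cp[j + 1L] - cp[j]) * (Tv[j + 1L] - Tv[j])
  }
  # On a clean monotone flank the innermost and outermost candidate
  # crossings coincide; under noise they bracket the true crossing with
  # opposite bias, so their mean is a nearly unbiased estimate.
  jl_in <- max(below_left)                       # walking out from the peak
  jl_out <- max(min(which(cp[seq_len(i)] >= half)) - 1L, 1L)  # from outside in
  t_left <- mean(c(cross_at(jl_in), cross_at(jl_out)))
  jr_in <- i - 1L + min(below_right)
  jr_out <- min(i - 1L + max(which(cp[seq(i, length(cp))] >= half)),
                length(cp) - 1L)
  t_right <- mean(c(cross_at(jr_in - 1L), cross_at(jr_out)))
  T_half <- t_right - t_left

  dH_cal <- sum(diff(Tv) * (utils::head(cp, -1) + utils::tail(cp, -1)) / 2)

  list(Tm = Tm, T_half = T_half, dH_cal = dH_cal)
}

#' Van't Hoff enthalpy from peak position and width
#'
#' The approximate two-state relation
#' \deqn{\Delta H_{VH} \approx 4 R T_m^2 / T_{1/2}.}
#' With R in cal mol^-1 K^-1 the result is reported in kcal/mol. Note the
#' factor 4 is an approximation: for an exact two-state transition the FWHM
#' obeys \eqn{T_{1/2} = 3.5255\,R T_m^2/\Delta H_{VH}}, so this estimator
#' over-reports a true two-state enthalpy by 4/3.5255 (about 13%); the
#' approximate form is the field's convention and is kept as is.
#'
#' @param Tm Transition temperature, K.
#' @param T_half Full width at half maximum, K.
#' @param R Gas constant, cal mol^-1 K^-1 (default 1.9872).
#' @return Van't Hoff enthalpy in kcal/mol.
#' @examples
#' vant_hoff_enthalpy(305.75, 9.80)  # ~75.8 kcal/mol
#' @export
vant_hoff_enthalpy <- function(Tm, T_half, R = 1.9872) {
  if (any(Tm <= 0)) stop("Tm must be > 0", call. = FALSE)
  if (any(T_half <= 0)) stop("T_half must be > 0", call. = FALSE)
  4 * R * Tm^2 / T_half / 1000
}

#' Cooperative unit
#'
#' Ratio of van't Hoff to calorimetric enthalpy: the effective number of
#' lipids undergoing the transition together. Reported rounded to the nearest
#' integer by convention; this function returns the unrounded ratio.
#'
#' @param dH_vH Van't Hoff enthalpy, kcal/mol.
#' @param dH_cal Calorimetric enthalpy, kcal/mol, > 0.
#' @return The dimensionless ratio `dH_vH / dH_cal`.
#' @examples
#' round(cooperative_unit(75.8, 1.4))  # 54
#' @export
cooperative_unit <- function(dH_vH, dH_cal) {
  if (any(dH_cal <= 0)) stop("dH_cal must be > 0", call. = FALSE)
  dH_vH / dH_cal
}

#' Full thermotropic analysis of one scan
#'
#' Chains [subtract_baseline()], [transition_parameters()],
#' [vant_hoff_enthalpy()] and [cooperative_unit()] on a raw thermogram.
#'
#' @inheritParams subtract_baseline
#' @inheritParams vant_hoff_enthalpy
#' @return A `dsc_transition`: list with `Tm`, `T_half`, `dH_cal`, `dH_vH`,
#'   `CU`.
#' @export
analyze_thermogram <- function(tg, T_low, T_high, R = 1.9872) {
  sub <- if (isTRUE(attr(tg, "baseline_subtracted"))) tg else
    subtract_baseline(tg, T_low, T_high)
  tp <- transition_parameters(sub, T_low, T_high)
  dH_vH <- vant_hoff_enthalpy(tp$Tm, tp$T_half, R)
  structure(
    list(Tm = tp$Tm, T_half = tp$T_half, dH_cal = tp$dH_cal, dH_vH = dH_vH,
         CU = cooperative_unit(dH_vH, tp$dH_cal)),
    class = "dsc_transition"
  )
}

#' @export
print.dsc_transition <- function(x, ...) {
  cat("<dsc_transition>\n")
  cat(sprintf("  Tm      = %.2f K (%.1f C)\n", x$Tm, x$Tm - 273.15))
  cat(sprintf("  T_1/2   = %.2f K\n", x$T_half))
  cat(sprintf("  dH_cal  = %.3g kcal/mol\n", x$dH_cal))
  cat(sprintf("  dH_vH   = %.3g kcal/mol\n", x$dH_vH))
  cat(sprintf("  CU      = %d\n", round(x$CU)))
  invisible(x)
}

#' @rdname analyze_thermogram
#' @param x A `dsc_transition`.
#' @param ... Unused.
#' @export
tidy.dsc_transition <- function(x, ...) {
  tibble::tibble(
    term = c("Tm", "T_half", "dH_cal", "dH_vH", "CU"),
    estimate = c(x$Tm, x$T_half, x$dH_cal, x$dH_vH, x$CU)
  )
}

#' Analyze replicate DSC scans
#'
#' Runs the full thermotropic chain on each scan and reports per-quantity
#' mean and sample standard deviation. The cooperative unit is averaged over
#' per-scan CU values (not computed from the ratio of mean enthalpies).
#' Scans failing the analysis (e.g. truncated peaks) are excluded with a
#' message; at least two scans must survive.
#'
#' @param scans List of `thermogram` objects.
#' @inheritParams analyze_thermogram
#' @return A tibble with one row per quantity (`Tm`, `T_half`, `dH_cal`,
#'   `dH_vH`, `CU`) and columns `mean`, `sd`, `n`.
#' @export
analyze_replicates <- function(scans, T_low, T_high, R = 1.9872) {
  if (length(scans) < 2L) stop("need at least 2 scans", call. = FALSE)
  per_scan <- purrr::imap(scans, function(tg, i) {
    tryCatch(analyze_thermogram(tg, T_low, T_high, R),
             error = function(e) {
               msg_info("scan ", i, " excluded: ", conditionMessage(e))
               NULL
             })
  })
  ok <- purrr::compact(per_scan)
  if (length(ok) == 0L) {
    stop("no scans survived analysis", call. = FALSE)
  }
  vals <- purrr::map(ok, ~ unlist(.x[c("Tm", "T_half", "dH_cal", "dH_vH", "CU")]))
  mat <- do.call(rbind, vals)
  tibble::tibble(
    term = colnames(mat),
    mean = unname(apply(mat, 2, mean)),
    sd = unname(apply(mat, 2, stats::sd)),
    n = nrow(mat)
  )
}
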