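test_that("chord baseline removes a linear ramp exactly", {
  tK <- seq(290, 320, by = 0.1)
  ramp <- make_thermogram(tK, 0.3 + 0.01 * tK)
  flat <- subtract_baseline(ramp, 292, 318)
  expect_equal(max(abs(flat$cp)), 0, tolerance = 1e-12)

  # a compact-support peak sitting on exact zeros is untouched in the window
  peak <- pmax(1 - ((tK - 305) / 5)^2, 0)
  tg <- make_thermogram(tK, peak)
  sub <- subtract_baseline(tg, 292, 318)
  inside <- tK >= 292 & tK <= 318
  expect_equal(sub$cp[inside], peak[inside], tolerance = 1e-12)
  expect_true(all(sub$cp[!inside] == 0))

  expect_error(subtract_baseline(tg, 280, 318), "outside the scan")
})

test_that("simulated endotherm plus ramp is recovered after baseline removal", {
  # anchors ~9 FWHM out, where the two-state tail is < 1e-10, so the chord
  # removes essentially exactly the ramp
  grid <- seq(215, 395, by = 0.05)
  sim_clean <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4,
                                   dH_vH_true = 66.8, T_grid = grid)
  sim_ramp <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4,
                                  dH_vH_true = 66.8, T_grid = grid,
                                  baseline_slope = 0.01)
  sub <- subtract_baseline(sim_ramp$thermogram, 220, 390)
  inside <- sub$temperature >= 220 & sub$temperature <= 390
  expect_lt(max(abs(sub$cp[inside] - sim_clean$thermogram$cp[inside])), 1e-10)
})

test_that("transition parameters match analytic two-state expectations", {
  sim <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8,
                             T_grid = seq(278.15, 328.15, by = 0.01))
  tg <- subtract_baseline(sim$thermogram, 280, 326)
  tp <- transition_parameters(tg, 280, 326)

  # oracle: argmax of the analytic excess-Cp curve on a dense grid -- the
  # 1/T^2 prefactor shifts it ~0.1 K below the nominal Tm
  R <- 1.9872
  dense <- seq(304, 307, by = 1e-4)
  K <- exp(-(66.8e3 / R) * (1 / dense - 1 / 305.75))
  cp_dense <- 1.4 * 66.8e3 / (R * dense^2) * K / (1 + K)^2
  tm_oracle <- dense[which.max(cp_dense)]
  expect_lt(abs(tp$Tm - tm_oracle), 0.02)
  a <- 66.8e3 / (R * 305.75^2)
  expect_equal(tm_oracle - 305.75, -4 / (305.75 * a^2), tolerance = 0.05)

  expect_equal(tp$dH_cal, 1.4, tolerance = 0.01)
  fwhm_analytic <- 3.5255 * R * 305.75^2 / 66.8e3
  expect_equal(tp$T_half, fwhm_analytic, tolerance = 0.01)
})

test_that("a symmetric triangular peak gives exact width and area", {
  tK <- seq(295, 305, by = 0.01)
  cp <- pmax(1 - abs(tK - 300), 0)
  tg <- subtract_baseline(make_thermogram(tK, cp), 296, 304)
  tp <- transition_parameters(tg, 296, 304)
  expect_equal(tp$Tm, 300, tolerance = 1e-6)
  expect_equal(tp$T_half, 1, tolerance = 1e-9)
  expect_equal(tp$dH_cal, 1, tolerance = 1e-9)
})

test_that("truncated peaks are refused", {
  sim <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8,
                             T_grid = seq(278.15, 328.15, by = 0.02))
  tg <- subtract_baseline(sim$thermogram, 280, 326)
  expect_error(transition_parameters(tg, 303, 326), "truncated")
})

test_that("van't Hoff arithmetic and proportionalities hold", {
  expect_equal(signif(vant_hoff_enthalpy(305.75, 9.80), 3), 75.8)
  x <- vant_hoff_enthalpy(300, 5)
  expect_equal(vant_hoff_enthalpy(300, 10), x / 2)
  expect_equal(vant_hoff_enthalpy(600, 5), 4 * x)
  expect_error(vant_hoff_enthalpy(300, 0), "T_half")
})

test_that("cooperative unit reproduces reported integer values", {
  expect_equal(round(cooperative_unit(75.8, 1.4)), 54)
  expect_equal(round(cooperative_unit(54.1, 1.3)), 42)
  expect_equal(round(cooperative_unit(41.2, 1.4)), 29)
  expect_equal(cooperative_unit(3.7, 3.7), 1)
  expect_error(cooperative_unit(10, 0), "dH_cal")
})

test_that("scaling Cp leaves Tm, T_half, dH_vH fixed and scales CU by 1/c", {
  grid <- seq(278.15, 328.15, by = 0.02)
  sim <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8,
                             T_grid = grid)
  base <- analyze_thermogram(sim$thermogram, 285, 325)
  for (c_scale in c(0.5, 3)) {
    scaled <- sim$thermogram
    scaled$cp <- scaled$cp * c_scale
    got <- analyze_thermogram(scaled, 285, 325)
    expect_equal(got$Tm, base$Tm, tolerance = 1e-9)
    expect_equal(got$T_half, base$T_half, tolerance = 1e-9)
    expect_equal(got$dH_vH, base$dH_vH, tolerance = 1e-9)
    expect_equal(got$dH_cal, base$dH_cal * c_scale, tolerance = 1e-9)
    expect_equal(got$CU, base$CU / c_scale, tolerance = 1e-9)
  }
})

test_that("calorimetric integral converges first-order in grid spacing", {
  err_at <- function(h) {
    sim <- simulate_thermogram(Tm = 305.75, dH_cal = 1.4, dH_vH_true = 66.8,
                               T_grid = seq(278.15, 328.15, by = h))
    tp <- transition_parameters(
      subtract_baseline(sim$thermogram, 280, 326), 280, 326)
    abs(tp$dH_cal - 1.4)
  }
  errs <- vapply(c(0.2, 0.1, 0.05), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01 * 1.4)
})

test_that("replicate analysis averages per scan and flags exclusions", {
  grid <- seq(278.15, 328.15, by = 0.05)
  identical_scans <- replicate(
    7, simulate_thermogram(305.75, 1.4, 66.8, T_grid = grid)$thermogram,
    simplify = FALSE)
  out <- analyze_replicates(identical_scans, 285, 325)
  expect_equal(out$sd, rep(0, 5))
  expect_equal(out$n, rep(7, 5))

  # jittered dH_cal: the replicate mean recovers the mean of the per-scan
  # generating enthalpies
  set.seed(11)
  dh_true <- 1.4 + runif(7, -0.3, 0.3)
  jittered <- lapply(dh_true, function(dh) {
    simulate_thermogram(305.75, dh, 66.8, T_grid = grid)$thermogram
  })
  out2 <- analyze_replicates(jittered, 285, 325)
  expect_lt(abs(out2$mean[out2$term == "dH_cal"] - mean(dh_true)), 0.1)

  # a truncated scan is excluded; the valid one carries the result
  narrow <- make_thermogram(seq(300, 328.15, by = 0.05),
                            simulate_thermogram(305.75, 1.4, 66.8,
                                                T_grid = grid)$thermogram$cp[
                              grid >= 300])
  suppressMessages(
    out3 <- analyze_replicates(list(identical_scans[[1]], narrow), 285, 325)
  )
  expect_equal(unique(out3$n), 1)
  expect_equal(out3$mean[out3$term == "Tm"],
               analyze_thermogram(identical_scans[[1]], 285, 325)$Tm)
})
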