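test_that("G factor calibration inverts the GP definition", {
  expect_equal(calibrate_g_factor(80, 100, reference_gp = 0), 0.8)
  expect_equal(calibrate_g_factor(100, 100, reference_gp = 0), 1)
  expect_error(calibrate_g_factor(100, 100, reference_gp = 1), "inside")

  # round trip: GP of the standard computed with the returned G equals the
  # reference exactly
  new <- membranalysis:::new_two_channel_image
  for (gp_ref in c(-0.4, 0, 0.3)) {
    g <- calibrate_g_factor(120, 85, reference_gp = gp_ref)
    std <- new(I440 = matrix(120, 3, 3), I490 = matrix(85, 3, 3))
    img <- compute_gp_image(std, g_factor = g, min_total_intensity = 1)
    expect_equal(unique(as.vector(img$gp)), gp_ref, tolerance = 1e-12)
  }
})

test_that("GP arithmetic: symmetry, thirds, and intensity-scale invariance", {
  new <- membranalysis:::new_two_channel_image
  eq <- new(I440 = matrix(50, 4, 4), I490 = matrix(50, 4, 4))
  expect_true(all(compute_gp_image(eq, 1, 1)$gp == 0))

  thr <- new(I440 = matrix(30, 4, 4), I490 = matrix(10, 4, 4))
  expect_true(all(compute_gp_image(thr, 1, 1)$gp == 0.5))

  # multiplying both channels by c > 0 leaves GP unchanged exactly
  base <- new(I440 = matrix(runif(64, 10, 200), 8, 8),
              I490 = matrix(runif(64, 10, 200), 8, 8))
  gp1 <- compute_gp_image(base, g_factor = 0.9, min_total_intensity = 0)
  for (c_scale in c(7, 0.5)) {
    scaled <- new(I440 = base$I440 * c_scale, I490 = base$I490 * c_scale)
    gp2 <- compute_gp_image(scaled, g_factor = 0.9, min_total_intensity = 0)
    expect_identical(gp1$gp, gp2$gp)
  }
  expect_true(all(abs(gp1$gp) <= 1))
})

test_that("low-intensity pixels are masked, never divided", {
  new <- membranalysis:::new_two_channel_image
  img <- new(I440 = matrix(c(0, 100), 1, 2), I490 = matrix(c(0, 100), 1, 2))
  gp <- compute_gp_image(img, 1, min_total_intensity = 10)
  expect_false(gp$valid_mask[1, 1])
  expect_true(is.na(gp$gp[1, 1]))
  expect_equal(gp$gp[1, 2], 0)
})

test_that("noisy synthetic frames recover the GP map within shot noise", {
  # 2000 counts/px: per-pixel GP shot noise sigma ~ 1/sqrt(S) = 0.022, so the
  # median absolute deviation (0.675 sigma) sits below 0.02
  sim <- simulate_guv_frames(n_frames = 1, step_frame = NULL,
                             mean_counts = 2000, seed = 3)
  gp <- compute_gp_image(sim$frames[[1]], g_factor = 1,
                         min_total_intensity = 400)
  truth <- sim$ground_truth
  # median absolute deviation from the piecewise-constant truth map
  n <- truth$image_size_px
  cc <- (n + 1) / 2
  rr <- sqrt((row(gp$gp) - cc)^2 + (col(gp$gp) - cc)^2)
  theta <- atan2(col(gp$gp) - cc, row(gp$gp) - cc) %% (2 * pi)
  on_ring <- abs(rr - truth$radius_px) <= truth$ring_width_px / 2
  truth_map <- ifelse(theta < 2 * pi * truth$arc_fraction_lo,
                      truth$gp_lo, truth$gp_ld)
  dev <- abs(gp$gp[on_ring] - truth_map[on_ring])
  expect_lt(median(dev, na.rm = TRUE), 0.02)
})

test_that("segmentation recovers the ordered-arc fraction and labels by GP", {
  sim <- simulate_guv_frames(n_frames = 1, step_frame = NULL, seed = 5)
  gp <- compute_gp_image(sim$frames[[1]], 1, min_total_intensity = 100)
  seg <- segment_vesicle_and_phases(gp, ring_width_px = 5)
  arc_frac <- sum(seg$lo_mask) / sum(seg$ring_mask)
  expect_lt(abs(arc_frac - 1 / 3), 0.05)
  s <- seg$stats
  expect_gte(s$gp_mean[s$region == "lo"], s$gp_mean[s$region == "ld"])
  expect_lt(abs(s$gp_mean[s$region == "lo"] - 0.45), 0.02)
  expect_lt(abs(s$gp_mean[s$region == "ld"] - 0.05), 0.02)
})

test_that("uniform-GP rings fall back to a near-degenerate split", {
  # a median split of pure shot noise separates the halves by ~1.6 sigma,
  # so high counts keep the degenerate lo/ld gap small
  sim <- simulate_guv_frames(n_frames = 1, step_frame = NULL, gp_lo = 0.2,
                             gp_ld = 0.2, mean_counts = 20000, seed = 9)
  gp <- compute_gp_image(sim$frames[[1]], 1, min_total_intensity = 4000)
  seg <- segment_vesicle_and_phases(gp, ring_width_px = 5)
  s <- seg$stats
  expect_lt(abs(s$gp_mean[s$region == "lo"] - s$gp_mean[s$region == "ld"]),
            0.02)
})

test_that("region statistics are rotation invariant", {
  sim <- simulate_guv_frames(n_frames = 1, step_frame = NULL, seed = 13)
  fr <- sim$frames[[1]]
  new <- membranalysis:::new_two_channel_image
  rot <- new(I440 = rot90(fr$I440), I490 = rot90(fr$I490))
  seg1 <- segment_vesicle_and_phases(
    compute_gp_image(fr, 1, 100), ring_width_px = 5)
  seg2 <- segment_vesicle_and_phases(
    compute_gp_image(rot, 1, 100), ring_width_px = 5)
  expect_equal(seg1$stats$gp_mean, seg2$stats$gp_mean, tolerance = 1e-6)
})

test_that("frames without a ring are refused", {
  new <- membranalysis:::new_two_channel_image
  dark <- new(I440 = matrix(5, 64, 64), I490 = matrix(5, 64, 64))
  gp <- compute_gp_image(dark, 1, min_total_intensity = 1)
  expect_error(segment_vesicle_and_phases(gp), "no ring")
})

test_that("GP time series bounds, degeneracy, and step response", {
  # single frame: whole-ring GP lies between the phase means
  sim1 <- simulate_guv_frames(n_frames = 1, step_frame = NULL, seed = 21)
  ts1 <- gp_timeseries(sim1$frames, g_factor = 1, min_total_intensity = 100)
  expect_equal(nrow(ts1), 1L)
  expect_gte(ts1$gp_whole_mean, ts1$gp_ld_mean)
  expect_lte(ts1$gp_whole_mean, ts1$gp_lo_mean)

  # identical frames: zero variance across rows
  frame <- simulate_guv_frames(n_frames = 1, step_frame = NULL,
                               seed = 22)$frames[[1]]
  ts2 <- gp_timeseries(list(frame, frame, frame), 1, 100)
  expect_equal(var(ts2$gp_lo_mean), 0)
  expect_equal(var(ts2$gp_whole_mean), 0)

  # +0.05 step at frame 3 appears in both phases at the right magnitude
  sim3 <- simulate_guv_frames(n_frames = 6, step_frame = 3,
                              step_delta_gp = 0.05, seed = 7)
  ts3 <- gp_timeseries(sim3$frames, 1, 100)
  pre <- ts3[1:2, ]; post <- ts3[3:6, ]
  expect_gte(mean(post$gp_lo_mean) - mean(pre$gp_lo_mean), 0.03)
  expect_lte(mean(post$gp_lo_mean) - mean(pre$gp_lo_mean), 0.07)
  expect_gte(mean(post$gp_ld_mean) - mean(pre$gp_ld_mean), 0.03)
  expect_lte(mean(post$gp_ld_mean) - mean(pre$gp_ld_mean), 0.07)

  # a dark (unsegmentable) frame yields a flagged row, series continues
  new <- membranalysis:::new_two_channel_image
  dark <- new(I440 = matrix(5, 128, 128), I490 = matrix(5, 128, 128),
              timestamp = 99)
  ts4 <- gp_timeseries(c(sim1$frames, list(dark)), 1, 100)
  expect_equal(ts4$segmented, c(TRUE, FALSE))
  expect_true(is.na(ts4$gp_lo_mean[2]))
})
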