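test_that("shifted subtraction pairs frames and restricts to the overlap", {
  run <- cached("tiny_linear_1", simulate_run(tiny_linear_cfg()))
  s <- run$sample
  zero <- shifted_subtract(s, s, 0L)
  expect_true(all(zero$I == 0))
  expect_identical(n_frames(zero), n_frames(s))
  sh <- shifted_subtract(s, s, 30L)
  expect_identical(frame_indices(sh)[1], 30L)
  expect_identical(n_frames(sh), n_frames(s) - 30L)
  # frame N minus frame N - shift
  expect_equal(get_frame(sh, 100)$I,
               get_frame(s, 100)$I - get_frame(s, 70)$I)
  expect_error(shifted_subtract(s, s, 600L), "overlap")
})

test_that("subtracting at the true shift removes the gradient trend", {
  cfg <- tiny_linear_cfg(noise_level = 0)
  run <- cached("tiny_linear_noiseless", simulate_run(cfg))
  sub <- shifted_subtract(run$sample, run$buffer, cfg$true_shift)
  # far off-peak frames: mid-band residual is numerically zero (the only
  # remaining signal is the sub-ppm tail of the elution peak itself)
  tr <- series_band_means(subset_series(sub, 45:80), default_bands()$mid)
  expect_lt(max(abs(tr$mean)), 1e-7)
})

test_that("ratio flatness separates constant, sloped and curved traces", {
  # constant ratio: flatness and curvature both ~0
  q <- seq(0.05, 3, length.out = 120)
  shape <- exp(-q^2)
  frames <- lapply(seq(1, 2, length.out = 40),
                   function(a) saxs_curve(q, a * shape, rep(0, 120)))
  ser <- series_from_curves(frames)
  rf <- ratio_flatness(ser, 0:39)
  expect_lt(rf$flatness, 1e-10)
  expect_lt(abs(rf$curvature), 1e-12)
  # scaling preserves the ratio: a sloped amplitude is still flat
  expect_lt(rf$constancy, 1e-10)
  # constructed parabola in the mid band only: positive flatness,
  # downward-opening low/mid trace => negative curvature
  x <- seq(-1, 1, length.out = 40)
  amp <- 1 + 0.5 * x^2   # mid band inflated at the edges -> low/mid dips there
  frames2 <- lapply(amp, function(a) {
    I <- shape
    I[q >= 1.5] <- I[q >= 1.5] * a
    saxs_curve(q, I, rep(0, 120))
  })
  rf2 <- ratio_flatness(series_from_curves(frames2), 0:39,
                        low = band_spec(0.11, 0.5), mid = band_spec(1.5, 2.5))
  expect_gt(rf2$flatness, 0)
  expect_lt(rf2$curvature, 0)
  expect_error(ratio_flatness(ser, 0:3), "at least 5")
})

test_that("deliberate background mis-scaling is classified under/over", {
  run <- cached("tiny_misscale", simulate_run(tiny_misscale_cfg()))
  roi <- default_roi(run$sample, run$buffer, frac = 0.5)
  under_b <- run$buffer; under_b$I <- under_b$I * 0.9
  over_b <- run$buffer; over_b$I <- over_b$I * 1.1
  shift <- run$config$true_shift
  rf_u <- ratio_flatness(shifted_subtract(run$sample, under_b, shift), roi)
  rf_o <- ratio_flatness(shifted_subtract(run$sample, over_b, shift), roi)
  expect_lt(rf_u$curvature, 0)   # concave: under-subtraction
  expect_gt(rf_o$curvature, 0)   # convex: over-subtraction
  # and the classifier agrees on a scan of the mis-scaled runs
  sc_u <- scan_shifts(run$sample, under_b, shifts = shift, roi = roi)
  sc_o <- scan_shifts(run$sample, over_b, shifts = shift, roi = roi)
  expect_identical(sc_u$classification[1], "under")
  expect_identical(sc_o$classification[1], "over")
})

test_that("noiseless shift scan recovers the exact generating offset", {
  run <- cached("tiny_linear_noiseless",
                simulate_run(tiny_linear_cfg(noise_level = 0)))
  scan <- scan_shifts(run$sample, run$buffer, shifts = tiny_shift_grid)
  expect_identical(scan$best_shift, 40L)
  # the flatness minimum at the truth is global over the grid
  expect_identical(which.min(scan$flatness),
                   which(scan$shifts == 40L))
  # runs whose background clocks agree (true shift zero): zero wins
  run0 <- cached("tiny_linear_shift0",
                 simulate_run(tiny_linear_cfg(seed = 2, true_shift = 0)))
  scan0 <- scan_shifts(run0$sample, run0$buffer,
                       shifts = seq(-20L, 20L, 5L))
  expect_lte(abs(scan0$best_shift), 5L)
})

test_that("scan agrees with the explicit subtract-then-score path", {
  run <- cached("tiny_linear_1", simulate_run(tiny_linear_cfg()))
  roi <- default_roi(run$sample, run$buffer)
  scan <- scan_shifts(run$sample, run$buffer, shifts = c(35L, 40L, 50L),
                      roi = roi)
  for (k in 1:3) {
    rf <- ratio_flatness(shifted_subtract(run$sample, run$buffer,
                                          scan$shifts[k]), roi)
    expect_equal(scan$flatness[k], rf$flatness, tolerance = 1e-10)
    expect_equal(scan$curvature[k], rf$curvature, tolerance = 1e-10)
  }
})

test_that("noisy shift recovery lands within ten frames of the truth", {
  hits <- 0L
  for (s in 1:6) {
    run <- simulate_run(tiny_linear_cfg(seed = s))
    scan <- scan_shifts(run$sample, run$buffer, shifts = tiny_shift_grid)
    if (abs(scan$best_shift - 40L) <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("a ten-frame mis-shift barely perturbs the averaged curve", {
  # systematic part: noiseless run shows a constant offset above 1 nm^-1
  run0 <- cached("tiny_linear_noiseless",
                 simulate_run(tiny_linear_cfg(noise_level = 0)))
  roi0 <- default_roi(run0$sample, run0$buffer)
  base0 <- average_frames(shifted_subtract(run0$sample, run0$buffer, 40L),
                          roi0)
  hi0 <- base0$q > 1
  for (d in c(-10L, 10L)) {
    off <- average_frames(shifted_subtract(run0$sample, run0$buffer,
                                           40L + d), roi0)
    diff <- off$I - base0$I
    expect_lt(stats::sd(diff[hi0]), 0.02 * abs(mean(diff[hi0])))
  }
  # noisy run: the perturbation stays below 1% of the recorded signal
  run <- cached("tiny_linear_1", simulate_run(tiny_linear_cfg()))
  scan <- scan_shifts(run$sample, run$buffer, shifts = tiny_shift_grid)
  roi <- scan$roi
  avg_best <- average_frames(shifted_subtract(run$sample, run$buffer,
                                              scan$best_shift), roi)
  raw_avg <- average_frames(run$sample, roi)
  hi <- avg_best$q > 1
  for (d in c(-10L, 10L)) {
    avg_off <- average_frames(shifted_subtract(run$sample, run$buffer,
                                               scan$best_shift + d), roi)
    diff <- avg_off$I - avg_best$I
    expect_lt(max(abs(diff[hi]) / raw_avg$I[hi]), 0.01)
  }
})

test_that("heterogeneous peaks are flagged, single species are not", {
  run1 <- cached("tiny_linear_full_1", simulate_run(sim_config(seed = 1)))
  sc1 <- cached("scan_full_1", scan_shifts(run1$sample, run1$buffer))
  h1 <- flag_heterogeneous_peak(sc1)
  expect_false(h1$heterogeneous)
  run2 <- cached("two_species_5", simulate_run(tiny_two_species_cfg(seed = 5)))
  sc2 <- cached("scan_two_species_5", scan_shifts(run2$sample, run2$buffer))
  h2 <- flag_heterogeneous_peak(sc2)
  expect_true(h2$heterogeneous)
  expect_match(h2$report, "heterogeneous")
  expect_error(flag_heterogeneous_peak(list()), "completed shift scan")
})
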