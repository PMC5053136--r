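test_that("scattering curve construction enforces its invariants", {
  expect_s3_class(saxs_curve(1:5 / 10, 5:1, rep(1, 5)), "saxs_curve")
  expect_error(saxs_curve(c(0.1, 0.1, 0.3), 1:3, rep(1, 3)), "increasing")
  expect_error(saxs_curve(1:3 / 10, 1:3, c(1, -1, 1)), "non-negative")
  expect_error(saxs_curve(1:3 / 10, c(1, NA, 3), rep(1, 3)), "finite")
  expect_error(saxs_curve(1:3 / 10, 1:4, rep(1, 3)), "equal length")
  # Angstrom input converts by exactly 10
  c_a <- saxs_curve(c(0.01, 0.02, 0.03), 1:3, rep(1, 3), units_q = "A^-1")
  expect_identical(c_a$q, c(0.1, 0.2, 0.3))
})

test_that("band means match a brute-force index-selection oracle", {
  set.seed(42)
  for (i in 1:100) {
    cv <- random_curve(n = sample(10:60, 1))
    lo <- stats::runif(1, 0, 4); hi <- lo + stats::runif(1, 0.2, 2)
    idx <- which(cv$q >= lo & cv$q <= hi)
    if (length(idx) == 0) {
      expect_error(band_mean(cv, band_spec(lo, hi)), "no grid points")
    } else {
      bm <- band_mean(cv, band_spec(lo, hi))
      expect_equal(bm$mean, mean(cv$I[idx]))
      expect_identical(bm$n, length(idx))
    }
  }
  # inclusive edges
  cv <- saxs_curve(1:5, rep(2, 5), rep(0, 5))
  expect_identical(band_mean(cv, band_spec(1, 3))$n, 3L)
})

test_that("curve subtraction propagates errors and respects grids", {
  cv <- random_curve(20)
  z <- subtract_curves(cv, cv)
  expect_true(all(z$I == 0))
  expect_equal(z$sigma, sqrt(2) * cv$sigma)
  # 3-4-5 quadrature
  a <- saxs_curve(1:5, rep(10, 5), rep(3, 5))
  b <- saxs_curve(1:5, rep(4, 5), rep(4, 5))
  d <- subtract_curves(a, b)
  expect_equal(d$I, rep(6, 5))
  expect_equal(d$sigma, rep(5, 5))
  # linearity: (a + b) - b == a exactly in intensity
  s <- saxs_curve(a$q, a$I + b$I, a$sigma)
  expect_identical(subtract_curves(s, b)$I, a$I)
  expect_error(subtract_curves(a, saxs_curve(1:6, rep(1, 6), rep(0, 6))),
               "grid mismatch")
  expect_error(subtract_curves(a, saxs_curve(a$q + 1e-6, b$I, b$sigma)),
               "grid mismatch")
})

test_that("curve averaging is exact, permutation-invariant and shrinks sigma", {
  cv <- random_curve(15)
  one <- average_curves(list(cv))
  expect_curves_equal(one, cv)
  n <- 4
  same <- average_curves(rep(list(cv), n))
  expect_equal(same$I, cv$I)
  expect_equal(same$sigma, cv$sigma / sqrt(n))
  a <- saxs_curve(1:5, rep(2, 5), rep(1, 5))
  b <- saxs_curve(1:5, rep(4, 5), rep(1, 5))
  expect_equal(average_curves(list(a, b))$I, rep(3, 5))
  curves <- replicate(5, random_curve(12), simplify = FALSE)
  for (i in 2:5) curves[[i]] <- saxs_curve(curves[[1]]$q, rnorm(12, 10),
                                           abs(rnorm(12, 1, 0.2)))
  perm <- sample(5)
  expect_curves_equal(average_curves(curves), average_curves(curves[perm]))
  expect_error(average_curves(list()), "empty")
})

test_that("low/mid ratio and trace normalization behave as documented", {
  cv <- saxs_curve(seq(0.05, 4.9, length.out = 200), rep(7, 200),
                   rep(0.1, 200))
  expect_equal(low_mid_ratio(cv)$ratio, 1)
  # 1/q^2-type curve against the brute-force quotient
  q <- seq(0.05, 4.9, length.out = 300)
  cv2 <- saxs_curve(q, 1 / q^2, rep(0.01, 300))
  b <- default_bands()
  il <- which(q >= 0.11 & q <= 0.5); im <- which(q >= 1.5 & q <= 2.5)
  expect_equal(low_mid_ratio(cv2)$ratio,
               mean(1 / q[il]^2) / mean(1 / q[im]^2))
  # perfect subtraction of a flat background: 0/0 is an error, not NaN
  flat0 <- saxs_curve(q, rep(0, 300), rep(0.1, 300))
  expect_error(low_mid_ratio(flat0), "mid-band mean is zero")

  expect_equal(normalize_traces(list(rep(7, 10)))[[1]], rep(1, 10))
  out <- normalize_traces(list(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(out[[1]], c(0.5, 1, 1.5))
  expect_equal(out[[2]], c(0.5, 1, 1.5))
  # roi restricted to a sub-range: means computed only there
  tr <- c(2, 2, 4, 4, 8)
  expect_equal(normalize_traces(list(tr), roi = 3:4)[[1]], tr / 4)
  expect_error(normalize_traces(list(rep(0, 5))), "zero")
})

test_that("gradient programs map frames to fractions and salt", {
  lin <- gradient_program(25, 1000, "linear",
                          list(start_frame = 0, end_frame = 1000,
                               f_start = 0, f_end = 1))
  expect_equal(fraction_at(lin, 500), 0.5)
  lin2 <- gradient_program(25, 1000, "linear",
                           list(start_frame = 0, end_frame = 975,
                                f_start = 0, f_end = 1))
  expect_equal(fraction_at(lin2, 98), 98 / 975)
  stp <- gradient_program(25, 1000, "step",
                          data.frame(start_frame = c(0, 1290), f = c(0, 0.12)))
  expect_equal(fraction_at(stp, 1289), 0)     # right-continuous plateaus
  expect_equal(fraction_at(stp, 1290), 0.12)
  expect_equal(salt_at(stp, 2000), 142)
  expect_equal(salt_at(lin, 0), 25)
  expect_equal(salt_at(lin, 1000), 1000)
  # monotone schedule -> monotone salt
  expect_true(all(diff(salt_at(lin, 0:1000)) >= 0))
  expect_error(gradient_program(25, 1000, "step",
                                data.frame(start_frame = c(0, 10), f = c(0, 1.2))),
               "\\[0, 1\\]")
  expect_error(gradient_program(1000, 25, "linear",
                                list(start_frame = 0, end_frame = 10,
                                     f_start = 0, f_end = 1)), "cB > cA")
})

test_that("frame counts convert linearly to elution volumes", {
  expect_equal(frames_to_volume(60, 1, 1), 1)
  expect_equal(frames_to_volume(130, 2, 1), 130 / 120)
  n <- c(10, 20, 40, 80)
  v <- frames_to_volume(n, 1, 1.5)
  expect_equal(v / n, rep(v[1] / n[1], 4))  # linear in n_frames
  expect_error(frames_to_volume(10, 0, 1), "positive")
})

test_that("frame series accessors and subsetting are consistent", {
  cfg <- tiny_linear_cfg()
  run <- cached("tiny_linear_1", simulate_run(tiny_linear_cfg()))
  s <- run$sample
  expect_identical(n_frames(s), 500L)
  f100 <- get_frame(s, 100)
  expect_equal(f100$I, s$I[, 101])
  sub <- subset_series(s, 100:120)
  expect_identical(frame_indices(sub), 100:120)
  expect_equal(get_frame(sub, 110)$I, get_frame(s, 110)$I)
  expect_error(subset_series(s, c(1, 3)), "contiguous")
  expect_error(get_frame(s, 1000), "outside")
  avg <- average_frames(s, 100:103)
  expect_equal(avg$I, rowMeans(s$I[, 101:104]))
  bm <- series_band_means(s, default_bands()$low)
  expect_equal(bm$mean[101],
               band_mean(f100, default_bands()$low)$mean)
})

test_that("beam passage time follows from capillary geometry", {
  # 1 ml/min through a 1.8 mm capillary, 700 um beam
  t <- beam_passage_time(1, 1.8, 700)
  expect_equal(t, 0.7 / ((1000 / 60) / (pi * 0.9^2)))
  expect_lt(abs(t - 0.107), 5e-4)
})

test_that("resampling is explicit linear interpolation and refuses extrapolation", {
  cv <- saxs_curve(1:10, (1:10)^2, rep(1, 10))
  r <- resample_curve(cv, c(1.5, 2.5, 7.5))
  expect_equal(r$I, c(2.5, 6.5, 56.5))
  expect_error(resample_curve(cv, c(0.5, 2)), "extrapolation")
})
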