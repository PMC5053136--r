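test_that("transition fit round-trips its own noiseless generator", {
  run <- cached("tiny_step_noiseless",
                simulate_run(tiny_step_cfg(noise_level = 0)))
  # blank run: the high-q trace is exactly the exponential model
  m <- fit_transition(run$buffer, tiny_step_regions$region_I,
                      tiny_step_regions$region_II)
  expect_lt(abs(m$N0 / 242 - 1), 1e-6)
  expect_lt(abs(m$Nprime / 10 - 1), 1e-6)
  expect_false(m$Nprime_flag)
})

test_that("a hard step collapses the fitted decay constant and is flagged", {
  run <- simulate_run(tiny_step_cfg(noise_level = 0,
                                    dispersion_Nprime = 1e-9))
  m <- fit_transition(run$buffer, tiny_step_regions$region_I,
                      tiny_step_regions$region_II)
  expect_lt(m$Nprime, 0.5)
  expect_true(m$Nprime_flag)
})

test_that("noisy transition fits recover onset and decay within the stated bands", {
  n0_ok <- np_ok <- 0L
  for (s in 1:6) {
    run <- simulate_run(tiny_step_cfg(seed = s))
    m <- fit_transition(run$sample, tiny_step_regions$region_I,
                        tiny_step_regions$region_II)
    if (abs(m$N0 - 242) <= 2) n0_ok <- n0_ok + 1L
    if (abs(m$Nprime - 10) <= 3) np_ok <- np_ok + 1L
  }
  expect_gte(n0_ok, 5L)
  expect_gte(np_ok, 5L)
})

test_that("fit preconditions are enforced", {
  run <- cached("tiny_step_1", simulate_run(tiny_step_cfg()))
  expect_error(fit_transition(run$sample, 250:300, 200:240), "strictly before")
  expect_error(fit_transition(run$sample, 1:3, 500:520), "at least 5")
})

test_that("interpolated buffer honours onset, half-life and asymptote", {
  run <- cached("tiny_step_noiseless",
                simulate_run(tiny_step_cfg(noise_level = 0)))
  m <- cached("tiny_step_model_noiseless",
              fit_transition(run$buffer, tiny_step_regions$region_I,
                             tiny_step_regions$region_II))
  expect_curves_equal(interpolated_buffer(m, m$N0), m$buffer_I, tol = 1e-12)
  mid <- interpolated_buffer(m, m$N0 + m$Nprime * log(2))
  expect_equal(mid$I, (m$buffer_I$I + m$buffer_II$I) / 2, tolerance = 1e-12)
  far <- interpolated_buffer(m, m$N0 + 1e6)
  expect_equal(far$I, m$buffer_II$I, tolerance = 1e-12)
  # bounded between I and II and monotone in N point-wise
  Ns <- m$N0 + c(0, 2, 5, 10, 30, 100)
  prev <- interpolated_buffer(m, Ns[1])
  for (N in Ns[-1]) {
    cur <- interpolated_buffer(m, N)
    lo <- pmin(m$buffer_I$I, m$buffer_II$I)
    hi <- pmax(m$buffer_I$I, m$buffer_II$I)
    expect_true(all(cur$I >= lo - 1e-12 & cur$I <= hi + 1e-12))
    s <- sign(m$buffer_II$I - m$buffer_I$I)
    expect_true(all(s * (cur$I - prev$I) >= -1e-12))
    prev <- cur
  }
})

test_that("frame-wise step subtraction recovers the pure protein component", {
  cfg <- tiny_step_cfg(noise_level = 0)
  run <- cached("tiny_step_noiseless", simulate_run(cfg))
  m <- cached("tiny_step_model_noiseless",
              fit_transition(run$buffer, tiny_step_regions$region_I,
                             tiny_step_regions$region_II))
  res <- framewise_subtract_step(run$sample, m, roi = 270:310)
  for (fr in c(280, 290, 300)) {
    truth <- true_protein_curve(cfg, fr)
    sub <- get_frame(res$subtracted, fr)
    for (b in list(default_bands()$low, default_bands()$mid)) {
      expect_lt(abs(band_mean(sub, b)$mean / band_mean(truth, b)$mean - 1),
                0.02)
    }
  }
})

test_that("residuals far from peak and step are consistent with zero", {
  run <- cached("tiny_step_1", simulate_run(tiny_step_cfg()))
  m <- fit_transition(run$sample, tiny_step_regions$region_I,
                      tiny_step_regions$region_II)
  res <- framewise_subtract_step(run$sample, m, roi = 60:140)
  tr <- series_band_means(res$subtracted, default_bands()$mid)
  se_mean <- sqrt(sum(tr$se^2)) / length(tr$se)
  expect_lt(abs(mean(tr$mean)), 2 * se_mean)
})

test_that("identical buffers reduce the model to plain subtraction", {
  run <- cached("tiny_step_1", simulate_run(tiny_step_cfg()))
  bI <- average_frames(run$sample, 160:219)
  m <- list(buffer_I = bI, buffer_II = bI, N0 = 242, Nprime = 10)
  class(m) <- "step_transition"
  res <- framewise_subtract_step(run$sample, m, roi = 280:300)
  plain <- subtract_curves(get_frame(run$sample, 290), bI)
  expect_equal(get_frame(res$subtracted, 290)$I, plain$I, tolerance = 1e-12)
})

test_that("mis-subtraction bounds bracket the model subtraction", {
  run <- cached("tiny_step_1", simulate_run(tiny_step_cfg()))
  m <- cached("tiny_step_model_1",
              fit_transition(run$sample, tiny_step_regions$region_I,
                             tiny_step_regions$region_II))
  frames <- 275:305
  avg <- average_frames(run$sample, frames)
  mb <- mis_subtraction_bounds(avg, m, frames)
  # identical buffers: all three subtractions coincide
  m0 <- m; m0$buffer_II <- m0$buffer_I
  mb0 <- mis_subtraction_bounds(avg, m0, frames)
  expect_equal(mb0$under$I, mb0$best$I, tolerance = 1e-12)
  expect_equal(mb0$over$I, mb0$best$I, tolerance = 1e-12)
  # above 1 nm^-1 the bound offsets are approximately constant
  expect_true(all(mb$report$cv_above < 0.10))
  expect_true(all(is.finite(mb$report$max_rel_dev_below)))
})

test_that("buffer matching selects by the high-q band and breaks ties low", {
  cfg <- tiny_step_cfg()
  run <- cached("tiny_step_1", simulate_run(cfg))
  avg <- average_frames(run$sample, 275:305)
  cands <- list(`100` = background_curve(cfg, 100),
                `142` = background_curve(cfg, 142),
                `200` = background_curve(cfg, 200))
  res <- match_buffer(avg, cands)
  expect_identical(res$best_label, "142")
  expect_identical(nrow(res$residuals), 3L)
  # exact background: residual zero (noiseless sample)
  run0 <- cached("tiny_step_noiseless",
                 simulate_run(tiny_step_cfg(noise_level = 0)))
  salt_peak <- effective_salt(tiny_step_cfg(), 400)
  bg <- background_curve(cfg, salt_peak)
  off_peak <- average_frames(run0$sample, 395:405)  # no protein there
  res0 <- match_buffer(off_peak, list(truth = bg, other = background_curve(cfg, 500)))
  expect_identical(res0$best_label, "truth")
  expect_lt(res0$residuals$residual[1], 1e-6)
  # single candidate returned with its residual
  res1 <- match_buffer(avg, cands[2])
  expect_identical(res1$best_label, "142")
  expect_error(match_buffer(avg, list()), "no candidate")
  # tie toward the lower salt label
  same <- list(`150` = bg, `120` = bg)
  expect_identical(match_buffer(off_peak, same)$best_label, "120")
})

test_that("bracketing returns salt neighbours and flags series edges", {
  cfg <- tiny_step_cfg()
  cands <- list(`100` = background_curve(cfg, 100),
                `142` = background_curve(cfg, 142),
                `200` = background_curve(cfg, 200))
  br <- bracket_buffers(cands, "142")
  expect_identical(br$lower_label, "100")
  expect_identical(br$higher_label, "200")
  expect_false(br$at_edge)
  edge <- bracket_buffers(cands, "100")
  expect_true(edge$at_edge)
  expect_true(is.na(edge$lower_label))
  expect_identical(edge$higher_label, "142")
  expect_error(bracket_buffers(cands[1], "100"), "at least 2")
})

test_that("a post-step overshoot defeats the exponential model", {
  # co-eluting ions add a transient high-q bump the two-buffer exponential
  # cannot describe; the fit's chi2 crosses the threshold that recommends
  # averaged-curve buffer matching instead
  run <- simulate_run(sim_config_step_hexamer(seed = 2))
  m <- fit_transition(run$sample, 1208:1267, 1600:1659)
  expect_gt(m$chi2, 5)
  run_b <- simulate_run(sim_config_step_bsa(seed = 2))
  m_b <- fit_transition(run_b$sample, 1208:1267, 1600:1659)
  expect_lt(m_b$chi2, 5)
})

test_that("half-life is Nprime log 2", {
  expect_equal(half_life(17), 17 * log(2))
  expect_equal(round(half_life(17)), 12)
  expect_equal(half_life(1), log(2))
  expect_equal(half_life(1 / log(2)), 1)
  expect_error(half_life(0), "positive")
})
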