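#' Fit the delayed exponential buffer transition across a salt step
#'
#' After a programmed salt step, the background at the measurement position
#' saturates slowly rather than jumping. The buffer-dominated high-q trace
#' y(N) (band mean above 4.5 nm^-1 by default) is modelled as
#' \deqn{y(N) = II - (II - I) \exp[-(N - N_0)/N'] \quad (N \ge N_0),\qquad
#'       y(N) = I \quad (N < N_0),}
#' where I and II are the scalar band means of the averaged buffer regions
#' before and after the peak (held fixed, not refit) and the free
#' parameters are the onset frame N0 and the decay constant N'. The fit is
#' bounded least squares with a multi-start over N0 on a 5-frame grid
#' across the window between the two regions.
#'
#' @param series the (unsubtracted) sample [frame_series].
#' @param region_I,region_II absolute frame indices (>= 5 each) of the
#'   pre-step and post-step buffer regions; region_I must end before
#'   region_II begins.
#' @param fit_band [band_spec] for the scalar trace; default the transition
#'   band (4.5 nm^-1 to the grid maximum).
#' @param fit_frames frames over which the model is fitted; default: from
#'   the start of region_I to the end of region_II.
#' @return object of class \code{step_transition}: \code{buffer_I},
#'   \code{buffer_II} ([saxs_curve] averages), \code{N0}, \code{Nprime},
#'   \code{chi2} (mean squared residual over the fitted frames divided by
#'   the mean trace variance), \code{fit_band}, \code{trace},
#'   \code{Nprime_flag} (TRUE when N' collapsed below 0.5 frames: a hard
#'   step).
#' @export
fit_transition <- function(series, region_I, region_II,
                           fit_band = default_bands(max(series$q))$transition,
                           fit_frames = NULL) {
  if (length(region_I) < 5 || length(region_II) < 5)
    stop("regions I and II must each contain at least 5 frames")
  if (max(region_I) >= min(region_II))
    stop("region_I must lie strictly before region_II")
  buffer_I <- average_frames(series, region_I)
  buffer_II <- average_frames(series, region_II)
  I_lvl <- band_mean(buffer_I, fit_band)$mean
  II_lvl <- band_mean(buffer_II, fit_band)$mean
  if (is.null(fit_frames)) fit_frames <- min(region_I):max(region_II)
  sub <- subset_series(series, fit_frames)
  tr <- series_band_means(sub, fit_band)
  y <- tr$mean; N <- tr$frames

  model_y <- function(N0, Np) {
    ifelse(N < N0, I_lvl,
           II_lvl - (II_lvl - I_lvl) * exp(-(N - N0) / Np))
  }
  lo_N0 <- max(region_I); hi_N0 <- min(region_II)
  Np_hi <- (hi_N0 - lo_N0) * 2
  # profile SSR: for a given onset, the decay constant is a smooth 1-D
  # problem; the model is non-convex in N0, so N0 gets a coarse grid
  # (every 5 frames) followed by a golden-section refinement
  prof <- function(N0) {
    o <- stats::optimize(function(Np) sum((y - model_y(N0, Np))^2),
                         c(1e-3, Np_hi), tol = 1e-10)
    list(ssr = o$objective, Np = o$minimum)
  }
  grid <- seq(lo_N0, hi_N0, by = 5)
  g_ssr <- vapply(grid, function(n0) prof(n0)$ssr, numeric(1))
  k <- which.min(g_ssr)
  lo_b <- grid[max(k - 1, 1)]; hi_b <- grid[min(k + 1, length(grid))]
  o <- stats::optimize(function(n0) prof(n0)$ssr, c(lo_b, hi_b), tol = 1e-8)
  N0 <- o$minimum
  inner <- prof(N0)
  Np <- inner$Np
  ssr_min <- inner$ssr
  if (!is.finite(ssr_min)) stop("transition fit failed to converge")

  var_y <- mean(tr$se^2)
  chi2 <- if (var_y > 0) (ssr_min / length(y)) / var_y else
    ssr_min / length(y)
  structure(list(buffer_I = buffer_I, buffer_II = buffer_II,
                 I_level = I_lvl, II_level = II_lvl,
                 N0 = N0, Nprime = Np, chi2 = chi2,
                 fit_band = fit_band,
                 trace = list(frames = N, y = y, se = tr$se,
                              fitted = model_y(N0, Np)),
                 region_I = range(region_I), region_II = range(region_II),
                 Nprime_flag = Np < 0.5),
            class = "step_transition")
}

#' @export
print.step_transition <- function(x, ...) {
  cat(sprintf(
    "<step_transition: N0 = %.2f, N' = %.2f frames (half-life %.1f), chi2 = %.3g%s>\n",
    x$N0, x$Nprime, half_life(x$Nprime), x$chi2,
    if (x$Nprime_flag) ", N' pinned: hard step" else ""))
  invisible(x)
}

#' Default buffer regions around a salt step
#'
#' Region I: 60 frames ending 20 frames before the programmed step.
#' Region II: 60 frames starting five half-lives after the (estimated)
#' onset. Intended for a first pass with a guessed N'; recompute once from
#' the fitted parameters.
#'
#' @param step_frame programmed step frame.
#' @param Nprime decay-constant estimate, frames.
#' @param n_region frames per region.
#' @param series optional [frame_series] used to clip region II to the run.
#' @return list with \code{region_I} and \code{region_II} index vectors.
#' @export
default_step_regions <- function(step_frame, Nprime = 20, n_region = 60,
                                 series = NULL) {
  rI_end <- floor(step_frame) - 20
  region_I <- (rI_end - n_region + 1):rI_end
  rII_start <- ceiling(step_frame + 5 * half_life(Nprime))
  region_II <- rII_start:(rII_start + n_region - 1)
  if (!is.null(series)) {
    top <- frame_indices(series)[n_frames(series)]
    region_II <- region_II[region_II <= top]
    region_I <- region_I[region_I >= frame_indices(series)[1]]
  }
  list(region_I = region_I, region_II = region_II)
}

#' Half-life of the buffer transition
#'
#' Frames for the background to move halfway from buffer I to buffer II:
#' \code{Nprime * ln 2}.
#'
#' @param Nprime exponential decay constant, frames (> 0).
#' @return half-life, frames.
#' @export
half_life <- function(Nprime) {
  if (!isTRUE(all(Nprime > 0))) stop("Nprime must be positive")
  Nprime * log(2)
}

#' Interpolated buffer at a frame
#'
#' Point-wise in q: buffer_I for N < N0, otherwise
#' \code{II(q) - [II(q) - I(q)] exp[-(N - N0)/N']}. The same (N0, N')
#' schedule applies at every q; sigma is interpolated with the same
#' weights.
#'
#' @param model a \code{step_transition} from [fit_transition()].
#' @param N frame number.
#' @return a [saxs_curve].
#' @export
interpolated_buffer <- function(model, N) {
  if (N < model$N0) return(model$buffer_I)
  w <- exp(-(N - model$N0) / model$Nprime)
  saxs_curve(model$buffer_I$q,
             model$buffer_II$I - (model$buffer_II$I - model$buffer_I$I) * w,
             model$buffer_II$sigma -
               (model$buffer_II$sigma - model$buffer_I$sigma) * w,
             units_I = model$buffer_I$units_I)
}

#' Frame-wise background subtraction with the interpolated buffer
#'
#' Subtracts each frame's [interpolated_buffer()] and reports the ratio
#' flatness diagnostics over the region of interest to confirm a stable
#' signal throughout the peak.
#'
#' @param series the sample [frame_series].
#' @param model a \code{step_transition}.
#' @param roi absolute frame indices for the diagnostics (and of the
#'   returned series); default: all frames.
#' @param low,mid diagnostic bands.
#' @return list with \code{subtracted} ([frame_series]) and
#'   \code{diagnostics} (the [ratio_flatness()] result, or NULL when the
#'   roi has no positive mid-band signal).
#' @export
framewise_subtract_step <- function(series, model, roi = NULL,
                                    low = default_bands()$low,
                                    mid = default_bands()$mid) {
  if (is.null(roi)) roi <- frame_indices(series)
  sub <- subset_series(series, roi)
  w <- ifelse(roi < model$N0, 1, exp(-(roi - model$N0) / model$Nprime))
  bI <- model$buffer_I$I; bII <- model$buffer_II$I
  bg <- outer(bII, rep(1, length(roi))) - outer(bII - bI, w)
  sI <- model$buffer_I$sigma; sII <- model$buffer_II$sigma
  bg_sig <- outer(sII, rep(1, length(roi))) - outer(sII - sI, w)
  out <- frame_series(series$q, sub$I - bg,
                      sqrt(sub$sigma^2 + bg_sig^2),
                      frame_rate = series$frame_rate,
                      flow_rate = series$flow_rate,
                      first_frame_index = roi[1], units_I = series$units_I)
  diag <- tryCatch(ratio_flatness(out, roi, low, mid),
                   error = function(e) NULL)
  list(subtracted = out, diagnostics = diag)
}

#' Over- and under-subtraction bounds for a step run
#'
#' Brackets the model-based subtraction of an averaged peak: over-subtract
#' with buffer II directly, under-subtract with the mean of buffers I and
#' II. Differences from the model subtraction are summarized split at q =
#' 1 nm^-1: above, buffer mismatch is an approximately constant offset
#' (mean, sd, coefficient of variation reported); below, the deviation is
#' q-dependent (maximum relative deviation reported).
#'
#' @param peak_average raw (unsubtracted) averaged sample curve.
#' @param model a \code{step_transition}.
#' @param frames the absolute frame indices that were averaged (used to
#'   average the interpolated buffer consistently).
#' @param q_split split point, nm^-1.
#' @return list with curves \code{best}, \code{under}, \code{over} and a
#'   \code{report} data.frame (one row per bound).
#' @export
mis_subtraction_bounds <- function(peak_average, model, frames,
                                   q_split = 1) {
  check_same_grid(peak_average, model$buffer_I,
                  what = "peak average and buffers")
  w <- ifelse(frames < model$N0, 1,
              exp(-(frames - model$N0) / model$Nprime))
  wbar <- mean(w)
  interp_avg <- saxs_curve(
    model$buffer_I$q,
    model$buffer_II$I - (model$buffer_II$I - model$buffer_I$I) * wbar,
    model$buffer_II$sigma -
      (model$buffer_II$sigma - model$buffer_I$sigma) * wbar)
  under_bg <- average_curves(list(model$buffer_I, model$buffer_II))
  best <- subtract_curves(peak_average, interp_avg)
  under <- subtract_curves(peak_average, under_bg)
  over <- subtract_curves(peak_average, model$buffer_II)

  summarize <- function(alt, label) {
    d <- alt$I - best$I
    hi <- peak_average$q > q_split
    lo <- !hi
    rel_lo <- abs(d[lo]) / pmax(abs(best$I[lo]), .Machine$double.eps)
    data.frame(bound = label,
               mean_diff_above = mean(d[hi]),
               sd_diff_above = stats::sd(d[hi]),
               cv_above = stats::sd(d[hi]) / abs(mean(d[hi])),
               max_rel_dev_below = max(rel_lo))
  }
  report <- rbind(summarize(under, "under (mean of I and II)"),
                  summarize(over, "over (buffer II)"))
  list(best = best, under = under, over = over, report = report)
}

#' Match a buffer from a salt series to an averaged sample
#'
#' Chooses the candidate whose mean scattering in the match band (4.25 to
#' 4.75 nm^-1 by default) is closest to the sample average's; ties break
#' toward the lower salt label. Used when irregular background changes
#' (e.g. a high-q overshoot from co-eluting ions) defeat frame-by-frame
#' modelling.
#'
#' @param sample_average averaged (unsubtracted) sample [saxs_curve].
#' @param candidates named list of candidate buffer curves; names are the
#'   salt labels (coerced to numeric for ordering when possible).
#' @param match_band [band_spec].
#' @return list with \code{best_label}, \code{best} (curve),
#'   \code{residuals} data.frame (label, band mean, |residual|).
#' @export
match_buffer <- function(sample_average, candidates,
                         match_band = default_bands()$match) {
  if (length(candidates) == 0) stop("no candidate buffers supplied")
  labels <- names(candidates)
  if (is.null(labels)) labels <- as.character(seq_along(candidates))
  target <- band_mean(sample_average, match_band)$mean
  bm <- vapply(candidates, function(c) band_mean(c, match_band)$mean,
               numeric(1))
  resid <- abs(bm - target)
  num <- suppressWarnings(as.numeric(labels))
  ord <- if (all(is.finite(num))) order(resid, num) else order(resid, labels)
  best <- ord[1]
  list(best_label = labels[best], best = candidates[[best]],
       residuals = data.frame(label = labels, band_mean = bm,
                              residual = resid, row.names = NULL))
}

#' Bracketing buffers around the matched salt step
#'
#' Returns the candidates adjacent (in salt) to the matched one, for
#' under/over-subtraction bounds. At a series end only the available side
#' is returned and the missing side is flagged.
#'
#' @param candidates named list of buffer curves ordered by salt (names
#'   are salt labels).
#' @param best_label label selected by [match_buffer()].
#' @return list with \code{lower}, \code{higher} (curves or NULL),
#'   \code{lower_label}, \code{higher_label}, \code{at_edge} (logical).
#' @export
bracket_buffers <- function(candidates, best_label) {
  if (length(candidates) < 2)
    stop("bracketing requires at least 2 candidates")
  labels <- names(candidates)
  num <- suppressWarnings(as.numeric(labels))
  if (all(is.finite(num))) {
    ord <- order(num); candidates <- candidates[ord]; labels <- labels[ord]
  }
  i <- match(best_label, labels)
  if (is.na(i)) stop(sprintf("label '%s' not among candidates", best_label))
  lower <- if (i > 1) candidates[[i - 1]] else NULL
  higher <- if (i < length(labels)) candidates[[i + 1]] else NULL
  list(lower = lower, higher = higher,
       lower_label = if (i > 1) labels[i - 1] else NA_character_,
       higher_label = if (i < length(labels)) labels[i + 1] else NA_character_,
       at_edge = is.null(lower) || is.null(higher))
}
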