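#' Subtract a shifted buffer run from a sample run
#'
#' Pairs sample frame N with buffer frame N - shift and subtracts
#' frame-wise. A positive shift means the matching background arrives later
#' in the sample run than in the buffer run, as observed when the blank
#' gradient leads the sample gradient. Output is restricted to the
#' overlapping frame range; uncertainties combine in quadrature.
#'
#' @param sample,buffer [frame_series] on one q grid.
#' @param shift integer frame offset.
#' @param min_overlap smallest acceptable number of overlapping frames.
#' @return a [frame_series] of subtracted frames (sample indexing).
#' @export
shifted_subtract <- function(sample, buffer, shift, min_overlap = 10) {
  check_same_grid(sample, buffer, what = "sample and buffer series")
  shift <- as.integer(round(shift))
  s_idx <- frame_indices(sample)
  b_idx <- frame_indices(buffer)
  keep <- (s_idx - shift) >= b_idx[1] & (s_idx - shift) <= b_idx[length(b_idx)]
  if (sum(keep) < min_overlap)
    stop(sprintf("insufficient overlap at shift %d: %d frames (need >= %d)",
                 shift, sum(keep), min_overlap))
  sc <- which(keep)
  bc <- col_of(buffer, s_idx[keep] - shift)
  frame_series(sample$q,
               sample$I[, sc, drop = FALSE] - buffer$I[, bc, drop = FALSE],
               sqrt(sample$sigma[, sc, drop = FALSE]^2 +
                      buffer$sigma[, bc, drop = FALSE]^2),
               frame_rate = sample$frame_rate, flow_rate = sample$flow_rate,
               first_frame_index = s_idx[keep][1], units_I = sample$units_I)
}

#' Flatness and curvature of the low/mid ratio trace
#'
#' Computes the per-frame low-q/mid-q ratio of a subtracted series over a
#' region of interest, normalizes the trace to mean 1 there, and fits (a) a
#' straight line in frame number, reporting the residual scatter about it
#' as the flatness metric (a parallel, possibly sloped line is the ideal;
#' curvature is not), and (b) a quadratic, reporting its second-order
#' coefficient with the sign convention of the low/mid trace: concave
#' (downward, negative coefficient) indicates under-subtraction, convex
#' indicates over-subtraction.
#'
#' Numerically the fits act on the inverse (mid/low) trace: across an
#' elution peak the low-q band carries strong protein signal while the
#' mid-q band is weak, so the conventional low/mid ratio divides by a
#' noisy, possibly vanishing denominator at the peak flanks, whereas
#' mid/low is well conditioned and a background mismatch enters it
#' linearly. To first order around a flat trace the two differ only in
#' sign of the deviations, so the reported curvature is the negated
#' quadratic coefficient of the inverse trace. When per-frame
#' uncertainties are available residuals are weighted by the propagated
#' standard error of each point, making the metric a reduced
#' (noise-relative) RMS with expectation ~1 for a perfect subtraction;
#' for noise-free input it falls back to the plain RMS residual.
#'
#' @param subtracted a background-corrected [frame_series].
#' @param roi absolute frame indices of the region of interest (>= 5).
#' @param low,mid diagnostic [band_spec]s.
#' @param max_undefined_frac largest tolerated fraction of roi frames with
#'   an undefined ratio (low- or mid-band mean <= 0).
#' @return list with \code{flatness}, \code{curvature} (low/mid sign
#'   convention), \code{trace} (normalized low/mid ratio, NA where
#'   undefined), \code{frames}, \code{ratio_se} (per-frame SE of the
#'   normalized ratio), \code{weighted}, \code{rms_trace} (unweighted RMS
#'   residual in trace units).
#' @export
ratio_flatness <- function(subtracted, roi,
                           low = default_bands()$low,
                           mid = default_bands()$mid,
                           max_undefined_frac = 0.1) {
  if (length(roi) < 5) stop("roi must contain at least 5 frames")
  sub <- subset_series(subtracted, roi)
  lo <- series_band_means(sub, low)
  mi <- series_band_means(sub, mid)
  bad <- !is.finite(mi$mean) | mi$mean <= 0 |
    !is.finite(lo$mean) | lo$mean <= 0
  if (mean(bad) > max_undefined_frac)
    stop(sprintf("undefined low/mid ratio on %.0f%% of roi frames",
                 100 * mean(bad)))
  ok <- !bad
  inv <- mi$mean / lo$mean             # well-conditioned working trace
  inv_se <- abs(inv) * sqrt((lo$se / lo$mean)^2 + (mi$se / mi$mean)^2)
  m_inv <- mean(inv[ok])
  y <- inv / m_inv
  y_se <- inv_se / abs(m_inv)
  x <- (roi - mean(roi))  # centred frame number
  weighted <- all(is.finite(y_se[ok]) & y_se[ok] > 0)
  w <- if (weighted) 1 / y_se[ok]^2 else rep(1, sum(ok))
  fit1 <- stats::lm.wfit(cbind(1, x[ok]), y[ok], w)
  flat <- if (weighted) sqrt(mean((fit1$residuals / y_se[ok])^2))
          else sqrt(mean(fit1$residuals^2))
  # constancy: residuals about the (weighted) mean -- slope NOT absorbed;
  # this is what distinguishes a drifting (heterogeneous) peak from a
  # merely sloped one
  res0 <- y[ok] - sum(w * y[ok]) / sum(w)
  constancy <- if (weighted) sqrt(mean((res0 / y_se[ok])^2))
               else sqrt(mean(res0^2))
  fit2 <- stats::lm.wfit(cbind(1, x[ok], x[ok]^2), y[ok], w)
  # reported trace in the conventional low/mid orientation
  ratio <- ifelse(bad, NA_real_, lo$mean / mi$mean)
  m <- mean(ratio[ok])
  list(flatness = flat, constancy = constancy, weighted = weighted,
       curvature = -unname(fit2$coefficients[3]),
       trace = ratio / m, frames = roi,
       ratio_se = ifelse(bad, NA_real_,
                         abs(ratio / m) * sqrt((lo$se / lo$mean)^2 +
                                                 (mi$se / mi$mean)^2)),
       rms_trace = sqrt(mean(fit1$residuals^2)),
       n_undefined = sum(bad))
}

#' Default region of interest for a run
#'
#' Frames where the low-band protein signal (sample minus unshifted buffer)
#' exceeds a fraction of its maximum: the elution peak. Deterministic and
#' shift-independent so one roi serves the whole scan.
#'
#' @param sample,buffer [frame_series].
#' @param frac threshold as a fraction of the peak maximum.
#' @param band [band_spec] used for the signal trace.
#' @return integer vector of absolute frame indices (largest contiguous
#'   block above threshold).
#' @export
default_roi <- function(sample, buffer, frac = 0.1,
                        band = default_bands()$low) {
  sub <- shifted_subtract(sample, buffer, 0L)
  tr <- series_band_means(sub, band)
  above <- tr$mean > frac * max(tr$mean)
  r <- rle(above)
  if (!any(r$values)) stop("no frames above threshold; no elution peak found")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  tr$frames[starts[best]:ends[best]]
}

#' Scan frame shifts between sample and buffer runs
#'
#' Evaluates [ratio_flatness()] for every shift on a grid (default -100 to
#' +300 in steps of 5 frames), picks the shift with the smallest flatness
#' metric (ties toward smaller |shift|), classifies each shift from the
#' sign of its curvature, and reports an uncertainty as the half-width of
#' the contiguous run of shifts whose metric lies within one standard error
#' of the minimum (floored at the grid step). Band means are linear in
#' intensity, so the scan computes per-frame band means of each run once
#' and differences them per shift.
#'
#' @param sample,buffer [frame_series].
#' @param shifts integer shift grid.
#' @param roi region of interest (absolute sample-frame indices); default
#'   [default_roi()].
#' @param low,mid diagnostic bands.
#' @param curvature_tol_factor classification threshold:
#'   |curvature| * (roi half-width)^2 < factor * flatness is "acceptable".
#' @return object of class \code{shift_scan} with \code{shifts},
#'   \code{flatness}, \code{curvature}, \code{classification},
#'   \code{best_shift}, \code{best_uncertainty}, \code{roi},
#'   \code{subtracted} (series at the best shift) and \code{best_flatness}.
#' @export
scan_shifts <- function(sample, buffer,
                        shifts = seq(-100L, 300L, by = 5L),
                        roi = NULL,
                        low = default_bands()$low,
                        mid = default_bands()$mid,
                        curvature_tol_factor = 2) {
  if (length(shifts) == 0) stop("empty shift grid")
  check_same_grid(sample, buffer, what = "sample and buffer series")
  if (is.null(roi)) roi <- default_roi(sample, buffer)
  s_lo <- series_band_means(sample, low)
  s_mi <- series_band_means(sample, mid)
  b_lo <- series_band_means(buffer, low)
  b_mi <- series_band_means(buffer, mid)
  b_first <- frame_indices(buffer)[1]

  x <- roi - mean(roi)
  X1 <- cbind(1, x); X2 <- cbind(1, x, x^2)
  half_w <- (max(roi) - min(roi)) / 2

  flat <- curv <- se_min <- rms_tr <- const <- rep(NA_real_, length(shifts))
  for (k in seq_along(shifts)) {
    b_frames <- roi - shifts[k]
    if (b_frames[1] < b_lo$frames[1] ||
        b_frames[length(b_frames)] > b_lo$frames[length(b_lo$frames)])
      next  # insufficient overlap at this shift
    si <- match(roi, s_lo$frames)
    bi <- b_frames - b_first + 1L
    lo_d <- s_lo$mean[si] - b_lo$mean[bi]
    mi_d <- s_mi$mean[si] - b_mi$mean[bi]
    ok <- is.finite(mi_d) & mi_d > 0 & is.finite(lo_d) & lo_d > 0
    if (mean(!ok) > 0.1) next
    # fit the well-conditioned inverse (mid/low) trace; see ratio_flatness
    inv <- mi_d / lo_d
    se_lo <- sqrt(s_lo$se[si]^2 + b_lo$se[bi]^2)
    se_mi <- sqrt(s_mi$se[si]^2 + b_mi$se[bi]^2)
    inv_se <- abs(inv) * sqrt((se_lo / lo_d)^2 + (se_mi / mi_d)^2)
    m <- mean(inv[ok]); y <- inv[ok] / m
    y_se <- inv_se[ok] / abs(m)
    weighted <- all(is.finite(y_se) & y_se > 0)
    w <- if (weighted) 1 / y_se^2 else rep(1, sum(ok))
    f1 <- stats::lm.wfit(X1[ok, , drop = FALSE], y, w)
    f2 <- stats::lm.wfit(X2[ok, , drop = FALSE], y, w)
    flat[k] <- if (weighted) sqrt(mean((f1$residuals / y_se)^2))
               else sqrt(mean(f1$residuals^2))
    res0 <- y - sum(w * y) / sum(w)
    const[k] <- if (weighted) sqrt(mean((res0 / y_se)^2))
                else sqrt(mean(res0^2))
    rms_tr[k] <- sqrt(mean(f1$residuals^2))  # trace units, for classification
    curv[k] <- -unname(f2$coefficients[3])   # low/mid sign convention
    # SE of the RMS-residual metric under iid noise: rms / sqrt(2 n)
    se_min[k] <- flat[k] / sqrt(2 * sum(ok))
  }
  if (all(is.na(flat))) stop("no shift on the grid satisfies the overlap precondition")

  cls <- ifelse(abs(curv) * half_w^2 < curvature_tol_factor * rms_tr,
                "acceptable", ifelse(curv < 0, "under", "over"))
  ord <- order(flat, abs(shifts), shifts)  # ties toward smaller |shift|
  best_k <- ord[1]
  best <- shifts[best_k]
  # contiguous run around the minimum within min + 1 SE
  tol <- flat[best_k] + se_min[best_k]
  within <- !is.na(flat) & flat <= tol
  lo_k <- best_k; while (lo_k > 1 && within[lo_k - 1]) lo_k <- lo_k - 1
  hi_k <- best_k; while (hi_k < length(shifts) && within[hi_k + 1]) hi_k <- hi_k + 1
  step <- if (length(shifts) > 1) min(diff(sort(shifts))) else 1
  unc <- max((shifts[hi_k] - shifts[lo_k]) / 2, step)

  structure(list(shifts = shifts, flatness = flat, constancy = const,
                 curvature = curv,
                 classification = cls, best_shift = best,
                 best_uncertainty = unc, best_flatness = flat[best_k],
                 roi = roi,
                 subtracted = shifted_subtract(sample, buffer, best),
                 low = low, mid = mid),
            class = "shift_scan")
}

#' @export
print.shift_scan <- function(x, ...) {
  cat(sprintf(
    "<shift_scan: best shift %d +/- %g frames, flatness %.4g, %d shifts tested>\n",
    x$best_shift, x$best_uncertainty, x$best_flatness,
    sum(!is.na(x$flatness))))
  invisible(x)
}

#' Flag a heterogeneous elution peak
#'
#' When no shift yields a constant ratio trace, the scattering is not
#' constant across the peak: more than one species co-elutes. The peak is
#' flagged when the smallest constancy metric (residual about the mean;
#' unlike the flatness metric used for shift selection, a drift/slope is
#' NOT tolerated here, because a monotone composition drift is exactly the
#' heterogeneity signature) over all shifts exceeds a threshold. With
#' noise-weighted metrics (the default for noisy data) constancy is a
#' reduced RMS with expectation ~1 for a stable signal and the default
#' threshold is 2; for unweighted (noise-free) input the default is 5x the
#' median per-frame standard error of the normalized ratio at the best
#' shift.
#'
#' @param scan a \code{shift_scan} from [scan_shifts()].
#' @param threshold absolute constancy threshold; \code{NULL} for the
#'   noise-derived default.
#' @param factor multiplier on the median ratio SE for the unweighted
#'   default threshold.
#' @return list with \code{heterogeneous} (logical), \code{min_constancy},
#'   \code{threshold} and a human-readable \code{report}.
#' @export
flag_heterogeneous_peak <- function(scan, threshold = NULL, factor = 5) {
  if (!inherits(scan, "shift_scan") || all(is.na(scan$constancy)))
    stop("flag_heterogeneous_peak needs a completed shift scan")
  minc <- min(scan$constancy, na.rm = TRUE)
  rf <- ratio_flatness(scan$subtracted, scan$roi, scan$low, scan$mid)
  if (is.null(threshold)) {
    threshold <- if (isTRUE(rf$weighted)) 2 else
      factor * stats::median(rf$ratio_se, na.rm = TRUE)
  }
  het <- minc > threshold
  list(heterogeneous = het, min_constancy = minc, threshold = threshold,
       report = sprintf(
         "roi frames %d..%d: min constancy %.4g %s threshold %.4g -> %s",
         min(scan$roi), max(scan$roi), minc,
         if (het) ">" else "<=", threshold,
         if (het) "peak heterogeneous (no shift gives a constant ratio)"
         else "single-species peak"))
}
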