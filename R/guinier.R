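#' Guinier fit over a fixed point range
#'
#' Weighted linear regression of \code{ln I} on \code{q^2} with weights
#' \code{(I/sigma)^2} (the delta-method weights for \code{ln I}); returns
#' \code{Rg = sqrt(-3 * slope)} and \code{I0 = exp(intercept)} with errors
#' from the regression covariance.
#'
#' @param curve a [saxs_curve].
#' @param i_range integer point indices (>= 5 points, all \code{I > 0}).
#' @return object of class \code{guinier_result}: \code{Rg}, \code{Rg_err}
#'   (nm), \code{I0}, \code{I0_err}, \code{i_min}, \code{i_max},
#'   \code{qRg_min}, \code{qRg_max}, \code{residuals} (per fitted point, in
#'   ln I), \code{r_squared}.
#' @export
guinier_fit <- function(curve, i_range) {
  i_range <- sort(unique(as.integer(i_range)))
  if (length(i_range) < 5) stop("Guinier fit needs at least 5 points")
  if (any(i_range < 1 | i_range > length(curve$q)))
    stop("i_range outside the curve")
  I <- curve$I[i_range]
  if (any(I <= 0)) stop("non-positive intensity in the Guinier range")
  q2 <- curve$q[i_range]^2
  y <- log(I)
  s <- curve$sigma[i_range]
  w <- if (all(s > 0)) (I / s)^2 else rep(1, length(I))
  W <- sum(w); xb <- sum(w * q2) / W; yb <- sum(w * y) / W
  Sxx <- sum(w * (q2 - xb)^2)
  if (Sxx <= 0) stop("degenerate q^2 range")
  slope <- sum(w * (q2 - xb) * (y - yb)) / Sxx
  intercept <- yb - slope * xb
  if (slope >= 0)
    stop("no Guinier decay in the selected range (slope >= 0)")
  resid <- y - (intercept + slope * q2)
  n <- length(y)
  # residual-scaled parameter errors (standard weighted-ls practice)
  s2 <- sum(w * resid^2) / max(n - 2, 1)
  slope_err <- sqrt(s2 / Sxx)
  int_err <- sqrt(s2 * (1 / W + xb^2 / Sxx))
  Rg <- sqrt(-3 * slope)
  I0 <- exp(intercept)
  ss_tot <- sum(w * (y - yb)^2)
  # reduced chi^2 in ln-space against the stated uncertainties
  chi2_red <- sum(resid^2 * w) / max(n - 2, 1)
  structure(list(
    Rg = Rg, Rg_err = 3 * slope_err / (2 * Rg),
    I0 = I0, I0_err = I0 * int_err,
    i_min = i_range[1], i_max = i_range[length(i_range)],
    qRg_min = curve$q[i_range[1]] * Rg,
    qRg_max = curve$q[i_range[length(i_range)]] * Rg,
    residuals = resid,
    chi2_red = chi2_red,
    r_squared = if (ss_tot > 0) 1 - sum(w * resid^2) / ss_tot else 1),
    class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "<guinier: Rg = %.3f +/- %.3f nm, I0 = %.4g +/- %.2g, qRg %.2f-%.2f (points %d-%d)>\n",
    x$Rg, x$Rg_err, x$I0, x$I0_err, x$qRg_min, x$qRg_max, x$i_min, x$i_max))
  invisible(x)
}

#' Automatic Guinier-region selection
#'
#' Deterministic search for the longest contiguous low-q window with
#' \code{qRg_max <= qRg_limit} (default 1.3), a stable Rg (change from the
#' window one point shorter below 5%) and acceptable fit quality. For each
#' candidate start point the window is grown greedily while the refitted
#' \code{q * Rg} stays within the limit and the reduced chi^2 against the
#' stated uncertainties stays below \code{chi2_max}: when the data carry
#' small uncertainties, systematic departure from the Guinier law
#' truncates the window before the nominal qRg limit. The longest
#' admissible window wins, ties going to the lowest starting q.
#'
#' @param curve a [saxs_curve].
#' @param qRg_limit upper bound on \code{q * Rg} in the fitted window.
#' @param min_points smallest admissible window.
#' @param min_r2 weighted R^2 threshold in ln-space.
#' @param chi2_max largest admissible reduced chi^2 (ignored when any
#'   sigma in the window is zero).
#' @param stability largest tolerated relative Rg change when the window
#'   grows by its final point.
#' @return a \code{guinier_result} (see [guinier_fit()]).
#' @export
auto_guinier <- function(curve, qRg_limit = 1.3, min_points = 10,
                         min_r2 = 0.5, chi2_max = 3, stability = 0.05) {
  n <- length(curve$q)
  # usable low-q stretch: leading run of positive intensities
  pos <- curve$I > 0
  m <- if (all(pos)) n else which(!pos)[1] - 1L
  if (m < min_points + 1)
    stop("no admissible Guinier window: too few positive low-q points")
  # rough Rg from a first coarse fit to cap the search region
  rough <- tryCatch(
    guinier_fit(curve, seq_len(min(max(min_points * 2, 20), m))),
    error = function(e) NULL)
  cap <- if (!is.null(rough)) {
    min(m, max(sum(curve$q <= 1.5 / rough$Rg), min_points + 5))
  } else m

  best <- NULL
  for (i_min in seq_len(max(cap - min_points, 1))) {
    i_max <- i_min + min_points - 1L
    if (i_max > cap) break
    use_chi2 <- all(curve$sigma[i_min:cap] > 0)
    fit <- tryCatch(guinier_fit(curve, i_min:i_max), error = function(e) NULL)
    if (is.null(fit)) next
    if (use_chi2 && fit$chi2_red > chi2_max) next
    prev <- fit
    # grow while the refit keeps qRg within the limit and the fit quality
    while (i_max < cap) {
      if (curve$q[i_max + 1L] * fit$Rg > qRg_limit) break
      cand <- tryCatch(guinier_fit(curve, i_min:(i_max + 1L)),
                       error = function(e) NULL)
      if (is.null(cand) || cand$qRg_max > qRg_limit + 1e-6) break
      if (use_chi2 && cand$chi2_red > chi2_max) break
      prev <- fit; fit <- cand; i_max <- i_max + 1L
    }
    if (fit$qRg_max > qRg_limit + 1e-6) next
    if (fit$r_squared < min_r2) next
    if (abs(fit$Rg - prev$Rg) / fit$Rg > stability) next
    len <- fit$i_max - fit$i_min + 1L
    if (is.null(best) || len > (best$i_max - best$i_min + 1L)) best <- fit
  }
  if (is.null(best))
    stop("no admissible Guinier window found")
  best
}
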