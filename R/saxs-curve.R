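#' One-dimensional scattering curve
#'
#' Container for a single azimuthally averaged SAXS pattern: momentum
#' transfer \code{q} (nm^-1, strictly increasing), intensity \code{I}
#' (arbitrary units or cm^-1, see \code{units_I}) and the per-point standard
#' error \code{sigma}.
#'
#' @param q numeric vector of momentum transfer values, nm^-1 by default,
#'   strictly increasing and finite.
#' @param I numeric vector of intensities, same length as \code{q}.
#' @param sigma numeric vector of per-point standard errors (>= 0). If
#'   omitted, \code{sqrt(abs(I))} is used and the curve is flagged as having
#'   synthetic uncertainties.
#' @param units_q unit of \code{q}: \code{"nm^-1"} (internal standard) or
#'   \code{"A^-1"}; Angstrom input is converted to nm^-1 (factor 10) on
#'   construction.
#' @param units_I unit tag for the intensity scale, informational
#'   (\code{"a.u."} or \code{"cm^-1"}).
#' @param meta named list of provenance metadata carried through I/O.
#' @return an object of class \code{saxs_curve}: a list with elements
#'   \code{q}, \code{I}, \code{sigma}, \code{units_I}, \code{meta}.
#' @export
saxs_curve <- function(q, I, sigma = NULL, units_q = c("nm^-1", "A^-1"),
                       units_I = "a.u.", meta = list()) {
  units_q <- match.arg(units_q)
  q <- as.numeric(q); I <- as.numeric(I)
  synthetic_sigma <- is.null(sigma)
  if (synthetic_sigma) sigma <- sqrt(abs(I))
  sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  if (!all(is.finite(q)) || !all(is.finite(I)) || !all(is.finite(sigma)))
    stop("q, I and sigma must be finite")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (units_q == "A^-1") q <- q * 10
  if (synthetic_sigma) meta$synthetic_sigma <- TRUE
  structure(list(q = q, I = I, sigma = sigma, units_I = units_I, meta = meta),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve: %d points, q = %.4g..%.4g nm^-1, I in %s>\n",
              length(x$q), x$q[1], x$q[length(x$q)], x$units_I))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' q-band specification
#'
#' A closed interval \code{[q_lo, q_hi]} in nm^-1 used to reduce a curve to a
#' scalar (band mean). Both edges are inclusive.
#'
#' @param q_lo,q_hi band edges, nm^-1, \code{0 <= q_lo < q_hi}.
#' @return object of class \code{band_spec}.
#' @seealso [default_bands()]
#' @export
band_spec <- function(q_lo, q_hi) {
  if (!is.finite(q_lo) || !is.finite(q_hi) || q_lo < 0 || q_lo >= q_hi)
    stop("band requires 0 <= q_lo < q_hi")
  structure(list(q_lo = q_lo, q_hi = q_hi), class = "band_spec")
}

#' Default q-bands for IEC-SAXS diagnostics
#'
#' The low-q band (0.11-0.5 nm^-1) tracks overall particle size, the mid-q
#' band (1.5-2.5 nm^-1) tracks shape features; their ratio is the per-frame
#' subtraction diagnostic. The transition band (4.5 nm^-1 to the grid
#' maximum) is buffer-dominated and feeds the step-transition fit; the match
#' band (4.25-4.75 nm^-1) is used for salt-series buffer matching.
#'
#' @param q_max upper edge used for the transition band, nm^-1.
#' @return named list of \code{band_spec}: \code{low}, \code{mid},
#'   \code{transition}, \code{match}.
#' @export
default_bands <- function(q_max = 4.9) {
  list(low = band_spec(0.11, 0.5),
       mid = band_spec(1.5, 2.5),
       transition = band_spec(4.5, q_max),
       match = band_spec(4.25, 4.75))
}

band_indices <- function(q, band) {
  which(q >= band$q_lo & q <= band$q_hi)
}

#' Mean intensity over a q-band
#'
#' Unweighted arithmetic mean of \code{I} over grid points with
#' \code{q_lo <= q <= q_hi} (inclusive edges).
#'
#' @param curve a [saxs_curve].
#' @param band a [band_spec].
#' @return list with \code{mean}, \code{n} (points in band) and \code{se}
#'   (standard error of the mean propagated from \code{sigma}).
#' @export
band_mean <- function(curve, band) {
  idx <- band_indices(curve$q, band)
  if (length(idx) == 0)
    stop(sprintf("band [%g, %g] contains no grid points (grid %g..%g nm^-1)",
                 band$q_lo, band$q_hi, curve$q[1], curve$q[length(curve$q)]))
  list(mean = mean(curve$I[idx]),
       n = length(idx),
       se = sqrt(sum(curve$sigma[idx]^2)) / length(idx))
}

check_same_grid <- function(a, b, rel_tol = 1e-9, what = "curves") {
  if (length(a$q) != length(b$q))
    stop(sprintf("grid mismatch between %s: %d vs %d points",
                 what, length(a$q), length(b$q)))
  scale <- pmax(abs(a$q), abs(b$q), 1e-300)
  if (any(abs(a$q - b$q) / scale > rel_tol))
    stop(sprintf("grid mismatch between %s: q values differ beyond tolerance",
                 what))
  invisible(TRUE)
}

#' Frame-wise curve subtraction
#'
#' Point-wise \code{I_sample - I_background} on a shared q grid with
#' uncertainties combined in quadrature. No resampling is performed; grids
#' must agree to a relative tolerance of 1e-9 per point (use
#' [resample_curve()] first if they do not).
#'
#' @param sample,background [saxs_curve] objects on the same grid.
#' @return a [saxs_curve] with the difference intensity.
#' @export
subtract_curves <- function(sample, background) {
  check_same_grid(sample, background, what = "sample and background")
  saxs_curve(sample$q, sample$I - background$I,
             sqrt(sample$sigma^2 + background$sigma^2),
             units_I = sample$units_I,
             meta = c(sample$meta, list(subtracted = TRUE)))
}

#' Average a list of curves
#'
#' Mean intensity with the standard error of the mean assuming independent
#' frames: \code{sigma_out = sqrt(sum(sigma_i^2)) / n}.
#'
#' @param curves non-empty list of [saxs_curve] objects on one grid.
#' @return averaged [saxs_curve].
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0) stop("cannot average an empty list of curves")
  ref <- curves[[1]]
  for (i in seq_along(curves)) check_same_grid(ref, curves[[i]], what = "curves")
  Im <- rowMeans(vapply(curves, function(c) c$I, numeric(length(ref$q))))
  sg <- sqrt(rowSums(vapply(curves, function(c) c$sigma^2,
                            numeric(length(ref$q))))) / length(curves)
  saxs_curve(ref$q, Im, sg, units_I = ref$units_I,
             meta = list(n_averaged = length(curves)))
}

#' Low-q to mid-q intensity ratio
#'
#' Scalar subtraction diagnostic: the ratio of the unweighted band mean in a
#' low-q region to that in a mid-q region. Constant across an elution peak
#' iff one species elutes with correct background subtraction.
#'
#' @param curve a [saxs_curve].
#' @param low,mid [band_spec]s; defaults are the standard diagnostic bands.
#' @return list with \code{ratio} and a first-order propagated \code{se}
#'   (diagnostic only).
#' @export
low_mid_ratio <- function(curve, low = default_bands()$low,
                          mid = default_bands()$mid) {
  lo <- band_mean(curve, low)
  mi <- band_mean(curve, mid)
  if (mi$mean == 0)
    stop("undefined low/mid ratio: mid-band mean is zero")
  r <- lo$mean / mi$mean
  se <- abs(r) * sqrt((lo$se / lo$mean)^2 + (mi$se / mi$mean)^2)
  list(ratio = r, se = se)
}

#' Normalize per-frame scalar traces to a common mean
#'
#' Each trace is divided by its own mean over the region of interest, so all
#' traces have mean 1 there; useful for overlaying ratio traces from
#' different subtractions.
#'
#' @param traces list of numeric vectors, all covering \code{roi}.
#' @param roi integer indices (positions within each trace) defining the
#'   region of interest; default: the full trace.
#' @return list of normalized traces in input order.
#' @export
normalize_traces <- function(traces, roi = NULL) {
  if (!is.list(traces)) traces <- list(traces)
  lapply(traces, function(tr) {
    idx <- if (is.null(roi)) seq_along(tr) else roi
    if (any(idx < 1 | idx > length(tr)))
      stop("roi extends beyond trace")
    m <- mean(tr[idx])
    if (m == 0) stop("cannot normalize: trace mean over roi is zero")
    tr / m
  })
}

#' Resample a curve onto a new q grid
#'
#' Explicit linear interpolation in q of both \code{I} and \code{sigma}.
#' Curve arithmetic in this package never resamples implicitly.
#'
#' @param curve a [saxs_curve].
#' @param q_new strictly increasing grid within the curve's q range.
#' @return a [saxs_curve] on \code{q_new}.
#' @export
resample_curve <- function(curve, q_new) {
  if (min(q_new) < curve$q[1] || max(q_new) > curve$q[length(curve$q)])
    stop("q_new extends beyond the measured range; extrapolation refused")
  saxs_curve(q_new,
             stats::approx(curve$q, curve$I, q_new)$y,
             stats::approx(curve$q, curve$sigma, q_new)$y,
             units_I = curve$units_I, meta = curve$meta)
}
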