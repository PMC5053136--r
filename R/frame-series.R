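#' Time-ordered series of scattering frames
#'
#' All frames share one q grid; intensities and uncertainties are stored as
#' matrices (rows = q points, columns = frames) for fast per-band reduction.
#' Frame indices are contiguous starting at \code{first_frame_index}.
#'
#' @param q shared momentum-transfer grid, nm^-1, strictly increasing.
#' @param I,sigma numeric matrices, \code{length(q)} rows, one column per
#'   frame.
#' @param frame_rate acquisition rate, Hz (> 0).
#' @param flow_rate chromatography flow rate, ml/min (> 0).
#' @param first_frame_index index of the first stored frame (default 0,
#'   matching beamline numbering).
#' @param units_I intensity unit tag.
#' @return object of class \code{frame_series}.
#' @export
frame_series <- function(q, I, sigma, frame_rate = 1, flow_rate = 1,
                         first_frame_index = 0L, units_I = "a.u.") {
  I <- as.matrix(I); sigma <- as.matrix(sigma)
  q <- as.numeric(q)
  if (nrow(I) != length(q) || !identical(dim(I), dim(sigma)))
    stop("I and sigma must be length(q) x n_frames matrices")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!isTRUE(frame_rate > 0) || !isTRUE(flow_rate > 0))
    stop("frame_rate and flow_rate must be positive")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(q = q, I = I, sigma = sigma,
                 frame_rate = frame_rate, flow_rate = flow_rate,
                 first_frame_index = as.integer(first_frame_index),
                 units_I = units_I),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf(
    "<frame_series: %d frames (%d..%d), %d q points, %.3g Hz, %.3g ml/min>\n",
    ncol(x$I), x$first_frame_index, x$first_frame_index + ncol(x$I) - 1L,
    length(x$q), x$frame_rate, x$flow_rate))
  invisible(x)
}

#' Number of frames in a series
#' @param series a [frame_series].
#' @return integer frame count.
#' @export
n_frames <- function(series) ncol(series$I)

#' Frame indices of a series
#' @param series a [frame_series].
#' @return integer vector of absolute frame indices.
#' @export
frame_indices <- function(series) {
  series$first_frame_index + seq_len(ncol(series$I)) - 1L
}

col_of <- function(series, frame) {
  col <- frame - series$first_frame_index + 1L
  if (any(col < 1 | col > ncol(series$I)))
    stop(sprintf("frame %s outside series range %d..%d",
                 paste(frame[col < 1 | col > ncol(series$I)], collapse = ","),
                 series$first_frame_index,
                 series$first_frame_index + ncol(series$I) - 1L))
  col
}

#' Extract one frame as a curve
#'
#' @param series a [frame_series].
#' @param frame absolute frame index.
#' @return a [saxs_curve].
#' @export
get_frame <- function(series, frame) {
  col <- col_of(series, frame)
  saxs_curve(series$q, series$I[, col], series$sigma[, col],
             units_I = series$units_I, meta = list(frame_index = frame))
}

#' Build a series from a list of curves
#'
#' @param curves list of [saxs_curve] on one grid, in frame order.
#' @param frame_rate,flow_rate,first_frame_index,units_I see [frame_series()].
#' @return a [frame_series].
#' @export
series_from_curves <- function(curves, frame_rate = 1, flow_rate = 1,
                               first_frame_index = 0L, units_I = "a.u.") {
  if (length(curves) == 0) stop("empty curve list")
  ref <- curves[[1]]
  for (i in seq_along(curves))
    check_same_grid(ref, curves[[i]],
                    what = sprintf("frames 1 and %d", i))
  frame_series(ref$q,
               vapply(curves, function(c) c$I, numeric(length(ref$q))),
               vapply(curves, function(c) c$sigma, numeric(length(ref$q))),
               frame_rate = frame_rate, flow_rate = flow_rate,
               first_frame_index = first_frame_index, units_I = units_I)
}

#' Per-frame band-mean trace
#'
#' Reduces every frame to its unweighted mean intensity over a q-band;
#' the workhorse behind ratio traces and the step-transition fit.
#'
#' @param series a [frame_series].
#' @param band a [band_spec].
#' @return list with \code{frames} (absolute indices), \code{mean} and
#'   \code{se} vectors.
#' @export
series_band_means <- function(series, band) {
  idx <- band_indices(series$q, band)
  if (length(idx) == 0)
    stop(sprintf("band [%g, %g] contains no grid points", band$q_lo, band$q_hi))
  list(frames = frame_indices(series),
       mean = colMeans(series$I[idx, , drop = FALSE]),
       se = sqrt(colSums(series$sigma[idx, , drop = FALSE]^2)) / length(idx))
}

#' Subset a series by absolute frame indices
#'
#' @param series a [frame_series].
#' @param frames contiguous absolute frame indices to keep.
#' @return a [frame_series].
#' @export
subset_series <- function(series, frames) {
  if (length(frames) == 0) stop("empty frame selection")
  if (any(diff(frames) != 1L)) stop("frame selection must be contiguous")
  cols <- col_of(series, frames)
  frame_series(series$q, series$I[, cols, drop = FALSE],
               series$sigma[, cols, drop = FALSE],
               frame_rate = series$frame_rate, flow_rate = series$flow_rate,
               first_frame_index = frames[1], units_I = series$units_I)
}

#' Average a contiguous frame range of a series
#'
#' @param series a [frame_series].
#' @param frames absolute frame indices to average.
#' @return a [saxs_curve] (mean intensity, standard error of the mean).
#' @export
average_frames <- function(series, frames) {
  cols <- col_of(series, frames)
  n <- length(cols)
  saxs_curve(series$q, rowMeans(series$I[, cols, drop = FALSE]),
             sqrt(rowSums(series$sigma[, cols, drop = FALSE]^2)) / n,
             units_I = series$units_I,
             meta = list(n_averaged = n, frames = range(frames)))
}
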