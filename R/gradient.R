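#' Salt-gradient program
#'
#' Describes how the mobile phase mixes buffer A (low salt) and buffer B
#' (high salt) as a function of frame number: either a linear ramp of the
#' buffer-B fraction or a stepwise schedule of plateaus. Step schedules are
#' right-continuous: a new fraction applies from its start frame inclusive.
#'
#' @param cA,cB NaCl concentrations of buffers A and B, mM (\code{cB > cA}).
#' @param mode \code{"linear"} or \code{"step"}.
#' @param schedule for linear mode a list/vector with
#'   \code{start_frame, end_frame, f_start, f_end}; for step mode a
#'   data.frame (or 2-column matrix) with columns \code{start_frame, f},
#'   start frames strictly increasing.
#' @return object of class \code{gradient_program}.
#' @export
gradient_program <- function(cA, cB, mode = c("linear", "step"), schedule) {
  mode <- match.arg(mode)
  if (!isTRUE(cB > cA)) stop("gradient requires cB > cA")
  if (mode == "linear") {
    s <- as.list(schedule)
    need <- c("start_frame", "end_frame", "f_start", "f_end")
    if (!all(need %in% names(s)))
      stop("linear schedule needs start_frame, end_frame, f_start, f_end")
    s <- s[need]
    if (s$end_frame <= s$start_frame)
      stop("linear schedule frames must increase")
    if (any(unlist(s[c("f_start", "f_end")]) < 0) ||
        any(unlist(s[c("f_start", "f_end")]) > 1))
      stop("buffer-B fraction must lie in [0, 1]")
    schedule <- s
  } else {
    schedule <- as.data.frame(schedule)
    names(schedule) <- c("start_frame", "f")
    if (nrow(schedule) < 1) stop("step schedule is empty")
    if (any(diff(schedule$start_frame) <= 0))
      stop("step schedule start frames must be strictly increasing")
    if (any(schedule$f < 0 | schedule$f > 1))
      stop("buffer-B fraction must lie in [0, 1]")
  }
  structure(list(cA = cA, cB = cB, mode = mode, schedule = schedule),
            class = "gradient_program")
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf("<gradient_program: %s, %g -> %g mM NaCl>\n",
              x$mode, x$cA, x$cB))
  invisible(x)
}

#' Buffer-B fraction at a frame
#'
#' Evaluates the gradient schedule. Linear mode interpolates linearly
#' between \code{f_start} and \code{f_end} (and holds the end values outside
#' the ramp but within coverage); step mode returns the plateau in force at
#' the frame, with the first plateau extended back to earlier frames.
#'
#' @param program a [gradient_program].
#' @param frame frame number(s); may be fractional.
#' @return buffer-B fraction(s) in \code{[0, 1]}.
#' @export
fraction_at <- function(program, frame) {
  if (program$mode == "linear") {
    s <- program$schedule
    if (any(frame < 0))
      stop("frame outside gradient coverage (negative frame)")
    f <- s$f_start + (frame - s$start_frame) /
      (s$end_frame - s$start_frame) * (s$f_end - s$f_start)
    pmin(pmax(f, min(s$f_start, s$f_end)), max(s$f_start, s$f_end))
  } else {
    s <- program$schedule
    i <- findInterval(frame, s$start_frame)
    s$f[pmax(i, 1L)]  # before the first entry: initial plateau
  }
}

#' Salt concentration at a frame
#'
#' Linear mixing rule: \code{c = cA + f * (cB - cA)} with \code{f} the
#' buffer-B fraction from the schedule.
#'
#' @param program a [gradient_program].
#' @param frame frame number(s).
#' @return NaCl concentration(s), mM.
#' @export
salt_at <- function(program, frame) {
  program$cA + fraction_at(program, frame) * (program$cB - program$cA)
}

#' Convert a frame count to an elution volume
#'
#' \code{volume = n_frames / frame_rate / 60 * flow_rate}.
#'
#' @param n_frames number of frames.
#' @param frame_rate acquisition rate, Hz.
#' @param flow_rate flow rate, ml/min.
#' @return volume, ml.
#' @export
frames_to_volume <- function(n_frames, frame_rate, flow_rate) {
  if (!isTRUE(frame_rate > 0) || !isTRUE(flow_rate > 0))
    stop("frame_rate and flow_rate must be positive")
  n_frames / frame_rate / 60 * flow_rate
}

#' Mean passage time of material through the beam
#'
#' Time for the eluent to traverse the X-ray beam footprint inside the
#' flow-through capillary: beam height divided by the mean linear flow speed
#' (volumetric flow over the capillary cross-section).
#'
#' @param flow_rate volumetric flow, ml/min.
#' @param capillary_diameter_mm inner diameter of the capillary, mm.
#' @param beam_size_um beam height along the flow direction, micrometres.
#' @return passage time, seconds.
#' @export
beam_passage_time <- function(flow_rate, capillary_diameter_mm = 1.8,
                              beam_size_um = 700) {
  if (!isTRUE(flow_rate > 0)) stop("flow_rate must be positive")
  area_mm2 <- pi * (capillary_diameter_mm / 2)^2
  speed_mm_s <- (flow_rate * 1000 / 60) / area_mm2  # ml/min -> mm^3/s
  (beam_size_um / 1000) / speed_mm_s
}
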