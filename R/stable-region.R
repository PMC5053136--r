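#' Stable-region selection for averaging
#'
#' Selects the largest contiguous frame range around the peak maximum in
#' which (a) every frame's CORMAP adjusted p-value against the reference
#' frame is at least \code{alpha} and (b) the normalized low/mid ratio
#' trace stays within a noise-aware tolerance band. Before the CORMAP
#' comparison each frame is scaled to the reference by the weighted
#' least-squares factor over the comparison q-range, so the test probes
#' shape identity rather than concentration (a factor estimated from a
#' narrow band would itself be noisy enough to correlate the point-wise
#' differences and inflate run lengths).
#'
#' @param series a background-corrected [frame_series].
#' @param reference absolute index of the reference frame; default: the
#'   frame with the largest low-band mean (peak maximum).
#' @param alpha significance level (default 0.01); a frame passes when
#'   \code{adjusted_p >= alpha}.
#' @param candidate_frames frames to consider; default: frames with
#'   low-band signal above 10% of the maximum.
#' @param ratio_k multiplier on the per-frame ratio SE for the tolerance
#'   band (floored at 5% relative).
#' @param low,mid diagnostic bands.
#' @param cormap_qmax restrict the CORMAP comparison to q below this value
#'   (the protein-dominated range), nm^-1.
#' @return list with \code{frames} (selected contiguous range, possibly
#'   empty), \code{reference}, \code{diagnostics} (per-candidate-frame
#'   data.frame with adjusted_p, normalized ratio, pass flags) and
#'   \code{report}.
#' @export
stable_region <- function(series, reference = NULL, alpha = 0.01,
                          candidate_frames = NULL, ratio_k = 4,
                          low = default_bands()$low,
                          mid = default_bands()$mid,
                          cormap_qmax = 2.5) {
  lo <- series_band_means(series, low)
  if (is.null(candidate_frames)) {
    above <- lo$mean > 0.1 * max(lo$mean)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0)
      return(list(frames = integer(0), reference = NA,
                  diagnostics = NULL, report = "no frames above threshold"))
    best <- runs[which.max(r$lengths[runs])]
    candidate_frames <- lo$frames[starts[best]:ends[best]]
  }
  ci <- match(candidate_frames, lo$frames)
  if (anyNA(ci))
    stop("candidate frames outside the series range")
  if (is.null(reference))
    reference <- candidate_frames[which.max(lo$mean[ci])]
  ref_curve <- get_frame(series, reference)

  qr <- c(min(series$q), cormap_qmax)
  in_qr <- series$q >= qr[1] & series$q <= qr[2]
  ref_I <- ref_curve$I[in_qr]
  wls <- 1 / pmax(ref_curve$sigma[in_qr]^2, .Machine$double.eps)
  cms <- vector("list", length(candidate_frames))
  for (k in seq_along(candidate_frames)) {
    fr <- get_frame(series, candidate_frames[k])
    f_I <- fr$I[in_qr]
    sc <- sum(wls * f_I * ref_I) / sum(wls * f_I^2)  # WLS scale to reference
    if (!is.finite(sc) || sc <= 0) sc <- 1           # no meaningful scale

    scaled <- saxs_curve(fr$q, fr$I * sc, fr$sigma * abs(sc))
    cms[[k]] <- cormap_compare(scaled, ref_curve, q_range = qr)
  }
  cms <- adjusted_pvalues(cms)
  adj <- vapply(cms, function(r) r$adjusted_p, numeric(1))

  rf <- tryCatch(ratio_flatness(series, candidate_frames, low, mid),
                 error = function(e) NULL)
  if (is.null(rf))
    return(list(frames = integer(0), reference = reference,
                diagnostics = NULL,
                report = "ratio undefined across the candidate frames; no stable region"))
  ref_pos <- match(reference, candidate_frames)
  ref_ratio <- rf$trace[ref_pos]
  tol <- pmax(ratio_k * sqrt(rf$ratio_se^2 + rf$ratio_se[ref_pos]^2), 0.05)
  ratio_ok <- abs(rf$trace - ref_ratio) <= tol
  ratio_ok[is.na(ratio_ok)] <- FALSE
  pass <- adj >= alpha & ratio_ok

  diagnostics <- data.frame(frame = candidate_frames, adjusted_p = adj,
                            norm_ratio = rf$trace, ratio_tol = tol,
                            cormap_pass = adj >= alpha,
                            ratio_pass = ratio_ok, pass = pass)
  # largest contiguous passing run containing (or nearest) the reference
  if (!any(pass)) {
    return(list(frames = integer(0), reference = reference,
                diagnostics = diagnostics,
                report = "no frame passes the stability criteria"))
  }
  r <- rle(pass)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  containing <- runs[starts[runs] <= ref_pos & ends[runs] >= ref_pos]
  chosen <- if (length(containing) > 0) containing else
    runs[which.max(r$lengths[runs])]
  frames <- candidate_frames[starts[chosen]:ends[chosen]]
  list(frames = frames, reference = reference, diagnostics = diagnostics,
       report = sprintf(
         "stable region: frames %d..%d (%d of %d candidates), reference %d, min adjusted p in region %.3g",
         min(frames), max(frames), length(frames),
         length(candidate_frames), reference,
         min(adj[candidate_frames %in% frames])))
}

#' Per-frame structural parameter table
#'
#' Runs [auto_guinier()] and [mass_from_vc()] on every frame of a
#' background-corrected series; frames where the Guinier search fails are
#' reported as missing rows, not dropped.
#'
#' @param series a background-corrected [frame_series].
#' @param roi absolute frame indices; default all frames.
#' @param mass_assumed molar mass (kDa) used for the concentration column;
#'   default: the per-frame Vc mass.
#' @return data.frame with columns \code{frame, I0, Rg, mass_vc,
#'   concentration} (NA where the fit failed).
#' @export
per_frame_parameters <- function(series, roi = NULL, mass_assumed = NULL) {
  if (is.null(roi)) roi <- frame_indices(series)
  out <- data.frame(frame = roi, I0 = NA_real_, Rg = NA_real_,
                    mass_vc = NA_real_, concentration = NA_real_)
  for (k in seq_along(roi)) {
    fr <- get_frame(series, roi[k])
    g <- tryCatch(auto_guinier(fr), error = function(e) NULL)
    if (is.null(g)) next
    out$I0[k] <- g$I0
    out$Rg[k] <- g$Rg
    mvc <- tryCatch(suppressWarnings(mass_from_vc(fr, g)),
                    error = function(e) NULL)
    if (!is.null(mvc)) out$mass_vc[k] <- mvc$mass_kda
    M <- if (is.null(mass_assumed)) out$mass_vc[k] else mass_assumed
    if (is.finite(M) && M > 0)
      out$concentration[k] <- concentration_from_forward(g$I0, M)
  }
  out
}
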