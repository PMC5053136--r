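#' Read a three-column SAXS curve
#'
#' Parses the community-standard whitespace-separated \code{q I sigma} text
#' format. Lines starting with \code{#} and blank lines are skipped; header
#' lines of the form \code{# key: value} are collected as metadata. A
#' \code{# units: 1/A} (or \code{A^-1}) header converts q to nm^-1 (factor
#' 10) on load. Two-column files are accepted with \code{sigma =
#' sqrt(|I|)}, flagged as synthetic in the metadata.
#'
#' @param path file to read.
#' @return a [saxs_curve].
#' @export
read_dat <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  payload <- character(0)
  payload_lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", kv))[[1]]
      if (length(m) == 3) meta[[m[2]]] <- m[3]
      next
    }
    payload <- c(payload, ln)
    payload_lineno <- c(payload_lineno, i)
  }
  if (length(payload) < 5)
    stop(sprintf("%s: fewer than 5 data points", path))
  fields <- strsplit(payload, "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 2))
    stop(sprintf("%s: line %d has fewer than 2 columns",
                 path, payload_lineno[which(ncols < 2)[1]]))
  two_col <- all(ncols == 2)
  vals <- suppressWarnings(lapply(fields, function(f) as.numeric(f[1:3])))
  q <- vapply(vals, `[`, numeric(1), 1)
  I <- vapply(vals, `[`, numeric(1), 2)
  s <- vapply(vals, `[`, numeric(1), 3)
  bad <- !is.finite(q) | !is.finite(I)
  if (any(bad))
    stop(sprintf("%s: non-numeric payload at line %d",
                 path, payload_lineno[which(bad)[1]]))
  if (two_col || all(!is.finite(s))) {
    s <- NULL
  } else if (any(!is.finite(s))) {
    stop(sprintf("%s: non-numeric sigma at line %d",
                 path, payload_lineno[which(!is.finite(s))[1]]))
  }
  units_q <- "nm^-1"
  u <- meta$units
  if (!is.null(u) && grepl("^(1/A|A\\^-1|1/angstrom)$", u, ignore.case = TRUE))
    units_q <- "A^-1"
  if (any(diff(q) <= 0))
    stop(sprintf("%s: q not strictly increasing at line %d",
                 path, payload_lineno[which(diff(q) <= 0)[1] + 1L]))
  saxs_curve(q, I, s, units_q = units_q,
             units_I = if (is.null(meta$units_I)) "a.u." else meta$units_I,
             meta = meta)
}

#' Write a curve as a three-column .dat file
#'
#' Three whitespace-separated columns (q, I, sigma) in scientific notation
#' with 12 significant digits; metadata written as \code{# key: value}
#' header lines. q is written in nm^-1 with a \code{# units: 1/nm} header.
#'
#' @param curve a [saxs_curve].
#' @param path output file.
#' @param header named list/character of extra metadata (e.g. frame index,
#'   subtraction provenance) to record in the header.
#' @return \code{path}, invisibly.
#' @export
write_dat <- function(curve, path, header = list()) {
  meta <- utils::modifyList(curve$meta, as.list(header))
  meta$units <- "1/nm"
  meta$units_I <- curve$units_I
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
    character(1))
  body <- sprintf("%.12e %.12e %.12e", curve$q, curve$I, curve$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a frame series as .dat files plus a CSV manifest
#'
#' One .dat per frame (\code{frame_NNNNNN.dat}) and a manifest CSV listing
#' \code{frame_index, filename, time_s} plus optional chromatogram columns.
#' Series metadata (frame_rate, flow_rate, first_frame_index) is stored as
#' \code{# key: value} comment lines at the top of the manifest and is
#' authoritative for frame/time/volume conversions.
#'
#' @param series a [frame_series].
#' @param dir output directory (created if needed).
#' @param manifest manifest filename within \code{dir}.
#' @param uv_au,conductivity_mS optional per-frame chromatogram traces.
#' @return path to the manifest, invisibly.
#' @export
write_series <- function(series, dir, manifest = "manifest.csv",
                         uv_au = NULL, conductivity_mS = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- frame_indices(series)
  files <- sprintf("frame_%06d.dat", idx)
  for (i in seq_along(idx))
    write_dat(get_frame(series, idx[i]), file.path(dir, files[i]),
              header = list(frame_index = idx[i]))
  df <- data.frame(frame_index = idx, filename = files,
                   time_s = idx / series$frame_rate)
  if (!is.null(uv_au)) df$uv_au <- uv_au
  if (!is.null(conductivity_mS)) df$conductivity_mS <- conductivity_mS
  mpath <- file.path(dir, manifest)
  con <- file(mpath, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %.10g", series$frame_rate),
               sprintf("# flow_rate: %.10g", series$flow_rate),
               sprintf("# units_I: %s", series$units_I)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a frame series from a manifest
#'
#' Reads the CSV manifest written by [write_series()] (or hand-authored in
#' the same layout), loads every referenced .dat file and assembles a
#' [frame_series]. Frame indices must be unique, sorted and contiguous; all
#' curves must share one q grid.
#'
#' @param manifest_path path to the manifest CSV.
#' @return a [frame_series].
#' @export
load_series <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("no such manifest: %s", manifest_path))
  lines <- readLines(manifest_path, warn = FALSE)
  meta <- list()
  for (ln in lines[startsWith(trimws(lines), "#")]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    m <- regmatches(kv, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", kv))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = lines[!startsWith(trimws(lines), "#")],
                        stringsAsFactors = FALSE)
  if (!all(c("frame_index", "filename") %in% names(df)))
    stop("manifest must have frame_index and filename columns")
  if (anyDuplicated(df$frame_index))
    stop("duplicate frame_index in manifest")
  df <- df[order(df$frame_index), , drop = FALSE]
  if (nrow(df) > 1 && any(diff(df$frame_index) != 1))
    stop(sprintf("non-contiguous frame indices in manifest (gap after frame %d)",
                 df$frame_index[which(diff(df$frame_index) != 1)[1]]))
  base <- dirname(manifest_path)
  curves <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    f <- file.path(base, df$filename[i])
    if (!file.exists(f))
      stop(sprintf("manifest references missing file: %s", df$filename[i]))
    curves[[i]] <- read_dat(f)
    if (i > 1) {
      ok <- tryCatch({check_same_grid(curves[[1]], curves[[i]]); TRUE},
                     error = function(e) FALSE)
      if (!ok)
        stop(sprintf("frame %d (%s) has a different q grid",
                     df$frame_index[i], df$filename[i]))
    }
  }
  fr <- if (is.null(meta$frame_rate)) 1 else as.numeric(meta$frame_rate)
  fl <- if (is.null(meta$flow_rate)) 1 else as.numeric(meta$flow_rate)
  series_from_curves(curves, frame_rate = fr, flow_rate = fl,
                     first_frame_index = df$frame_index[1],
                     units_I = if (is.null(meta$units_I)) "a.u." else meta$units_I)
}

#' Load a gradient program from a YAML config
#'
#' Expected keys: \code{cA}, \code{cB} (mM), \code{mode} ("linear" or
#' "step"), and \code{schedule}. For linear mode, schedule holds
#' \code{start_frame, end_frame, f_start, f_end}; for step mode, a list of
#' \code{\{start_frame, f\}} entries.
#'
#' @param config_path YAML file.
#' @return a validated [gradient_program].
#' @export
load_gradient <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (k in c("cA", "cB", "mode", "schedule"))
    if (is.null(cfg[[k]]))
      stop(sprintf("gradient config missing key '%s'", k))
  sched <- cfg$schedule
  if (identical(cfg$mode, "step"))
    sched <- do.call(rbind, lapply(sched, function(s)
      data.frame(start_frame = s$start_frame, f = s$f)))
  gradient_program(cfg$cA, cfg$cB, cfg$mode, sched)
}

#' Write a gradient program as YAML
#' @param program a [gradient_program].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gradient <- function(program, path) {
  sched <- if (program$mode == "step") {
    lapply(seq_len(nrow(program$schedule)), function(i)
      list(start_frame = program$schedule$start_frame[i],
           f = program$schedule$f[i]))
  } else program$schedule
  yaml::write_yaml(list(cA = program$cA, cB = program$cB,
                        mode = program$mode, schedule = sched), path)
  invisible(path)
}
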