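#' Read and write time traces as annotated CSV
#'
#' The on-disk format is a plain CSV with `#`-prefixed metadata header
#' lines followed by a `time_s,value` table. The sampling rate is mandatory
#' (`# fs_hz=<rate>`); the start time (`# t0_s=<t>`) defaults to the first
#' time value. Times must be non-decreasing.
#'
#' @param trace a [time_trace()].
#' @param path file path.
#' @return `write_time_trace` returns `path` invisibly; `read_time_trace`
#'   returns a [time_trace()].
#' @export
write_time_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.17g", trace$sampling_rate), con)
  writeLines(sprintf("# t0_s=%.17g", trace$start_time), con)
  writeLines("time_s,value", con)
  utils::write.table(
    data.frame(time_s = trace_times(trace), value = trace$values),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_time_trace
#' @export
read_time_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  fs_line <- grep("^#\\s*fs_hz=", meta, value = TRUE)
  if (!length(fs_line))
    stop("format error: missing `# fs_hz=` header in ", path, call. = FALSE)
  fs <- as.numeric(sub("^#\\s*fs_hz=", "", fs_line[1]))
  if (!is.finite(fs) || fs <= 0)
    stop("format error: invalid sampling rate header", call. = FALSE)
  t0_line <- grep("^#\\s*t0_s=", meta, value = TRUE)

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("format error: no data rows in ", path, call. = FALSE)
  has_header <- grepl("^[A-Za-z]", body[1])
  rows <- if (has_header) body[-1] else body
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("format error: malformed row(s) at line(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  tt <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  vv <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(tt) || anyNA(vv))
    stop("format error: non-numeric values in data rows", call. = FALSE)
  if (is.unsorted(tt))
    stop("format error: time column must be non-decreasing", call. = FALSE)
  t0 <- if (length(t0_line))
    as.numeric(sub("^#\\s*t0_s=", "", t0_line[1])) else tt[1]
  time_trace(vv, fs, start_time = t0)
}

#' Read and write beat tables as CSV
#'
#' @param beats a [beat_table()].
#' @param path file path.
#' @return `read_beat_table` returns a [beat_table()].
#' @export
write_beat_table <- function(beats, path) {
  stopifnot(inherits(beats, "beat_table"))
  utils::write.csv(as.data.frame(beats), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("r_peak_time_s", "p_peak_time_s", "label", "r_duration_ms",
            "pr_interval_ms", "matched_pulse_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  beat_table(df$r_peak_time_s, df$p_peak_time_s, df$label,
             df$r_duration_ms, df$pr_interval_ms, df$matched_pulse_index)
}

#' Export and re-import a peak list for manual curation
#'
#' Automated peak detection is curated by exporting the peak times to CSV,
#' editing the file by hand (deleting spurious rows, adjusting times), and
#' re-importing. The round trip with no edits is the identity.
#'
#' @param times numeric peak times, seconds.
#' @param path file path.
#' @return `read_peaks` returns the sorted numeric peak times.
#' @export
write_peaks <- function(times, path) {
  utils::write.csv(data.frame(peak_time_s = as.numeric(times)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path)
  if (!"peak_time_s" %in% names(df))
    stop("format error: missing `peak_time_s` column", call. = FALSE)
  sort(as.numeric(df$peak_time_s))
}

#' Read and write frame stacks as multi-page TIFF with a JSON sidecar
#'
#' Pixels are stored as 16-bit grayscale TIFF pages, linearly mapped from
#' the data range recorded in the sidecar; acquisition metadata
#' (`pixel_size_um`, `frame_rate_hz`, optional `exclusion`) lives in a JSON
#' sidecar (`<path>.json`) rather than TIFF tags, for portability.
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `read_stack` returns a [frame_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  rng <- range(stack$frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(n_frames(stack)), function(k) {
    (stack$frames[, , k] - rng[1]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_rate_hz = stack$frame_rate,
               value_min = rng[1], value_scale = scale,
               exclusion = stack$exclusion)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @param sidecar sidecar path; defaults to `<path>.json`.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("metadata sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("pixel_size_um", "frame_rate_hz"))
    if (is.null(meta[[f]]))
      stop("metadata error: missing field `", f, "` in sidecar",
           call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("format error: ragged page shapes in ", path, call. = FALSE)
  v0 <- if (is.null(meta$value_min)) 0 else meta$value_min
  sc <- if (is.null(meta$value_scale)) 1 else meta$value_scale
  frames <- array(unlist(pages), dim = c(shp, length(pages))) * sc + v0
  excl <- if (length(meta$exclusion)) as.numeric(meta$exclusion) else NULL
  frame_stack(frames, meta$frame_rate_hz, meta$pixel_size_um, excl)
}

#' Write a generator ground-truth record as JSON
#'
#' Serializes the ground-truth list returned by the synthetic-data
#' generators. Function-valued entries (analytic kernels, modulation
#' functions) and the embedded spec object are dropped; everything else is
#' written as plain JSON.
#'
#' @param truth ground-truth list from a generator.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- truth[!vapply(truth, is.function, logical(1))]
  keep$spec <- NULL
  if (inherits(keep$pulses, "pulse_train")) keep$pulses <- unclass(keep$pulses)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Write an aligned average as CSV
#'
#' Columns `lag_s`, `mean`, `sd`; the beat count and laser-onset/offset
#' summary go into `#` header lines.
#'
#' @param avg an [aligned_average()] result.
#' @param path file path.
#' @export
write_aligned_average <- function(avg, path) {
  stopifnot(inherits(avg, "aligned_average"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_beats=%d", avg$n_beats), con)
  writeLines(sprintf("# laser_onset_mean_s=%.9g", avg$laser_onset_mean_s), con)
  writeLines(sprintf("# laser_onset_sd_s=%.9g", avg$laser_onset_sd_s), con)
  writeLines(sprintf("# laser_offset_mean_s=%.9g", avg$laser_offset_mean_s),
             con)
  writeLines(sprintf("# laser_offset_sd_s=%.9g", avg$laser_offset_sd_s), con)
  writeLines("lag_s,mean,sd", con)
  utils::write.table(data.frame(avg$lag_s, avg$mean, avg$sd), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
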