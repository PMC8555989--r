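#' Assign each image line a cardiac phase from the ECG
#'
#' The cardiac cycle is defined by the R-peak times: a line acquired at
#' time `t` between consecutive R peaks `R_prev` and `R_next` gets phase
#' `(t - R_prev) / (R_next - R_prev)`, so phase 0 falls on the R peak.
#' Lines acquired before the first or at/after the last R peak cannot be
#' bracketed and get `NA`.
#'
#' @param line_times line acquisition times, s.
#' @param r_peaks sorted R-peak times, s (at least 2).
#' @return numeric vector of phases in `[0, 1)`, `NA` where unassignable.
#' @export
assign_cardiac_phase <- function(line_times, r_peaks) {
  if (length(r_peaks) < 2L)
    stop("need at least two R peaks to define a cardiac cycle", call. = FALSE)
  if (is.unsorted(r_peaks, strictly = TRUE))
    stop("r_peaks must be strictly increasing", call. = FALSE)
  i <- findInterval(line_times, r_peaks)
  phase <- rep(NA_real_, length(line_times))
  ok <- i >= 1L & i < length(r_peaks)
  phase[ok] <- (line_times[ok] - r_peaks[i[ok]]) /
    (r_peaks[i[ok] + 1L] - r_peaks[i[ok]])
  phase
}

#' Reject lines acquired during a respiratory exclusion window
#'
#' Detects respiration peaks (inspiration) in the respiratory trace and
#' rejects every line whose respiratory phase lies inside a window of total
#' width `exclusion_fraction` of the cycle, centered on the peak. Lines
#' outside the span of detected peaks are accepted. When no peaks are found
#' at all, every line is accepted with a warning.
#'
#' @param line_times line acquisition times, s.
#' @param resp a [time_trace()] of the respiratory signal covering the
#'   lines.
#' @param exclusion_fraction total rejected fraction of each respiratory
#'   cycle, in `[0, 1]` (default 0.3).
#' @param min_period_s minimum credible respiratory period used to debounce
#'   peak detection, s (default 0.25).
#' @return logical accept mask, one element per line.
#' @export
respiratory_gate <- function(line_times, resp, exclusion_fraction = 0.3,
                             min_period_s = 0.25) {
  stopifnot(inherits(resp, "time_trace"))
  if (exclusion_fraction < 0 || exclusion_fraction > 1)
    stop("exclusion_fraction must be in [0, 1]", call. = FALSE)
  if (exclusion_fraction == 0) return(rep(TRUE, length(line_times)))
  v <- resp$values
  rng <- range(v)
  mpd <- max(1L, round(min_period_s * resp$sampling_rate))
  pk <- if (diff(rng) > 0)
    pracma::findpeaks(v, minpeakheight = rng[1] + 0.5 * diff(rng),
                      minpeakdistance = mpd)
  else NULL
  if (is.null(pk) || nrow(pk) < 1L) {
    warning("no respiratory peaks found; accepting all lines")
    return(rep(TRUE, length(line_times)))
  }
  peaks <- sort(trace_times(resp)[pk[, 2L]])
  half <- exclusion_fraction / 2
  accept <- rep(TRUE, length(line_times))
  if (length(peaks) >= 2L) {
    ## phase relative to the bracketing peaks; reject phase < half or
    ## phase > 1 - half (window centered on the peak)
    i <- findInterval(line_times, peaks)
    inside <- i >= 1L & i < length(peaks)
    ph <- rep(NA_real_, length(line_times))
    ph[inside] <- (line_times[inside] - peaks[i[inside]]) /
      (peaks[i[inside] + 1L] - peaks[i[inside]])
    accept[inside] <- ph[inside] > half & ph[inside] < 1 - half
    ## before the first / after the last peak: use the adjacent period
    per1 <- peaks[2L] - peaks[1L]
    perN <- peaks[length(peaks)] - peaks[length(peaks) - 1L]
    pre <- i < 1L
    accept[pre] <- (peaks[1L] - line_times[pre]) > half * per1
    post <- i >= length(peaks)
    accept[post] <- (line_times[post] - peaks[length(peaks)]) > half * perN
  } else {
    ## single peak: reject within half a nominal window either side
    accept <- abs(line_times - peaks) > half * 2 * min_period_s
  }
  accept
}

#' Reconstruct phase-binned frames from gated image lines
#'
#' Places every accepted, phase-assigned line into the cardiac-phase bin
#' `floor(phase * n_bins)` at its row position, and averages the pixel
#' values of all lines contributing to the same (bin, row). The result is
#' one motion-frozen mean image per phase bin — with the default 10 bins,
#' one image per 10% increment of the cardiac cycle — plus the per-bin
#' per-row contributing-line counts. Rows that receive no line in a bin
#' are `NA` with count 0.
#'
#' @param lines a `line_record_set` (see [synth_linescan()]).
#' @param phases per-line cardiac phase from [assign_cardiac_phase()].
#' @param accept logical per-line accept mask (e.g. from
#'   [respiratory_gate()]); default all accepted.
#' @param n_bins number of phase bins (default 10).
#' @return object of class `phase_binned_stack`: list with `means` (list of
#'   `n_bins` matrices `rows_per_frame x n_cols`), `counts` (matrix
#'   `n_bins x rows_per_frame`), `n_bins`.
#' @export
reconstruct_phase_bins <- function(lines, phases, accept = NULL,
                                   n_bins = 10) {
  stopifnot(inherits(lines, "line_record_set"))
  n_lines <- nrow(lines$pixels)
  if (length(phases) != n_lines)
    stop("`phases` must have one value per line", call. = FALSE)
  if (is.null(accept)) accept <- rep(TRUE, n_lines)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)

  nr <- lines$rows_per_frame
  nc <- lines$n_cols
  sums <- array(0, dim = c(n_bins, nr, nc))
  counts <- matrix(0L, n_bins, nr)
  use <- which(accept & !is.na(phases))
  bin <- pmin(floor(phases * n_bins), n_bins - 1L) + 1L
  for (j in use) {
    b <- bin[j]; r <- lines$row_index[j] + 1L
    sums[b, r, ] <- sums[b, r, ] + lines$pixels[j, ]
    counts[b, r] <- counts[b, r] + 1L
  }
  means <- lapply(seq_len(n_bins), function(b) {
    m <- sums[b, , , drop = TRUE]
    m <- matrix(m, nr, nc)
    m <- m / counts[b, ]
    m[counts[b, ] == 0L, ] <- NA_real_
    m
  })
  structure(list(means = means, counts = counts, n_bins = as.integer(n_bins)),
            class = "phase_binned_stack")
}

#' @export
print.phase_binned_stack <- function(x, ...) {
  cat(sprintf("<phase_binned_stack> %d bins, %d x %d px, %d lines total\n",
              x$n_bins, nrow(x$means[[1]]), ncol(x$means[[1]]),
              sum(x$counts)))
  invisible(x)
}
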