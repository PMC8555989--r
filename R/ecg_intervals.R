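#' Measure R-wave duration and PR interval by zero-crossing interpolation
#'
#' On an ECG normalized to median zero (see [preprocess_ecg()]), the R-wave
#' duration of a beat is the time between the zero crossings immediately
#' flanking its R peak, and the PR interval is the time from the P-wave peak
#' to the first zero crossing of the QRS complex (the crossing immediately
#' preceding the R upstroke). Crossings are located by marching outward from
#' the R peak to the first sign change and linearly interpolating between
#' the bracketing samples.
#'
#' Beats for which a flanking crossing cannot be found within `search_span`
#' ms of the peak keep `NA` intervals and are flagged in the `flagged`
#' attribute of the result.
#'
#' @param ecg a preprocessed [time_trace()] (median zero).
#' @param beats a [beat_table()] with `r_peak_time_s` and (optionally)
#'   `p_peak_time_s` filled in.
#' @param search_span how far each side of the R peak to search for a zero
#'   crossing, ms (default 60).
#' @return the beat table with `r_duration_ms` and `pr_interval_ms` filled
#'   in; attribute `flagged` holds the row indices of beats with a missing
#'   crossing.
#' @export
measure_intervals <- function(ecg, beats, search_span = 60) {
  stopifnot(inherits(ecg, "time_trace"), inherits(beats, "beat_table"))
  v <- ecg$values
  fs <- ecg$sampling_rate
  n <- length(v)
  span <- max(1L, round(search_span / 1000 * fs))
  flagged <- integer(0)

  for (i in seq_len(nrow(beats))) {
    ip <- round((beats$r_peak_time_s[i] - ecg$start_time) * fs) + 1L
    if (ip < 2L || ip > n - 1L) { flagged <- c(flagged, i); next }
    ## snap to the local maximum within +/-2 samples of the nominal peak
    lo <- max(1L, ip - 2L); hi <- min(n, ip + 2L)
    ip <- lo + which.max(v[lo:hi]) - 1L
    if (v[ip] <= 0) { flagged <- c(flagged, i); next }

    iL <- ip
    while (iL > max(1L, ip - span) && v[iL - 1L] > 0) iL <- iL - 1L
    iR <- ip
    while (iR < min(n, ip + span) && v[iR + 1L] > 0) iR <- iR + 1L
    okL <- iL > 1L && v[iL - 1L] <= 0
    okR <- iR < n && v[iR + 1L] <= 0
    if (!okL || !okR) { flagged <- c(flagged, i); next }

    tL <- zero_cross_time(v[iL - 1L], v[iL], iL - 1L, fs, ecg$start_time)
    tR <- zero_cross_time(v[iR], v[iR + 1L], iR, fs, ecg$start_time)
    beats$r_duration_ms[i] <- (tR - tL) * 1000
    if (!is.na(beats$p_peak_time_s[i])) {
      pr <- (tL - beats$p_peak_time_s[i]) * 1000
      beats$pr_interval_ms[i] <- if (pr > 0) pr else NA_real_
    }
  }
  attr(beats, "flagged") <- flagged
  beats
}

## time at which the line through samples (i, v1) and (i+1, v2) crosses zero
zero_cross_time <- function(v1, v2, i1, fs, t0) {
  t0 + (i1 - 1L + (0 - v1) / (v2 - v1)) / fs
}

#' Event-aligned average of an ECG trace
#'
#' Extracts fixed windows around a set of alignment times (typically R-peak
#' or P-peak times of one beat class), and returns the mean and standard
#' deviation per lag, together with the mean and SD of the nearest laser
#' pulse onset and offset lags — the quantities plotted in a stimulated
#' versus unstimulated beat-average comparison.
#'
#' @param ecg a [time_trace()].
#' @param align_times alignment times, seconds; segments extending outside
#'   the trace are dropped.
#' @param window `c(pre_ms, post_ms)`, extents before/after the alignment
#'   point (both positive).
#' @param pulses optional [pulse_train()]; when supplied, the lag of the
#'   nearest pulse onset/offset to each alignment point is summarized.
#' @return object of class `aligned_average`: list with `lag_s`, `mean`,
#'   `sd`, `n_beats`, `laser_onset_mean_s`, `laser_onset_sd_s`,
#'   `laser_offset_mean_s`, `laser_offset_sd_s`.
#' @export
aligned_average <- function(ecg, align_times, window = c(60, 60),
                            pulses = NULL) {
  stopifnot(inherits(ecg, "time_trace"), length(window) == 2L,
            all(window > 0))
  fs <- ecg$sampling_rate
  npre <- round(window[1] / 1000 * fs)
  npost <- round(window[2] / 1000 * fs)
  n <- length(ecg$values)
  segs <- list()
  used <- numeric(0)
  for (a in align_times) {
    ic <- round((a - ecg$start_time) * fs) + 1L
    if (ic - npre < 1L || ic + npost > n) next
    segs[[length(segs) + 1L]] <- ecg$values[(ic - npre):(ic + npost)]
    used <- c(used, a)
  }
  if (length(segs) < 1L)
    stop("no usable segments: all windows fall outside the trace",
         call. = FALSE)
  m <- do.call(rbind, segs)
  lag <- ((-npre):npost) / fs
  res <- list(lag_s = lag,
              mean = colMeans(m),
              sd = apply(m, 2, stats::sd),
              n_beats = nrow(m),
              laser_onset_mean_s = NA_real_, laser_onset_sd_s = NA_real_,
              laser_offset_mean_s = NA_real_, laser_offset_sd_s = NA_real_)
  if (nrow(m) == 1L) res$sd <- rep(0, ncol(m))
  if (!is.null(pulses) && length(pulses$rising_edges)) {
    nearest_lag <- function(edges) {
      vapply(used, function(a) edges[which.min(abs(edges - a))] - a,
             numeric(1))
    }
    on <- nearest_lag(pulses$rising_edges)
    off <- nearest_lag(pulses$falling_edges)
    res$laser_onset_mean_s <- mean(on)
    res$laser_onset_sd_s <- if (length(on) > 1L) stats::sd(on) else 0
    res$laser_offset_mean_s <- mean(off)
    res$laser_offset_sd_s <- if (length(off) > 1L) stats::sd(off) else 0
  }
  class(res) <- "aligned_average"
  res
}

#' @export
print.aligned_average <- function(x, ...) {
  cat(sprintf(
    "<aligned_average> %d beats, lag [%.1f, %.1f] ms, laser onset %.1f ms\n",
    x$n_beats, 1000 * min(x$lag_s), 1000 * max(x$lag_s),
    1000 * x$laser_onset_mean_s))
  invisible(x)
}
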