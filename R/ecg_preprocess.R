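#' Preprocess a raw ECG trace
#'
#' Standard conditioning applied before peak detection and interval
#' measurement: (1) resample onto a uniform grid at `target_rate` by linear
#' interpolation (handles non-continuous recordings; gaps longer than two
#' sample periods are flagged in the `gaps` attribute), (2) lowpass filter
#' with a zero-phase 4th-order Butterworth at `passband` Hz (applied
#' forward-backward so intervals are not phase-shifted), (3) optionally
#' invert, and (4) shift and scale so the output has median zero and maximum
#' absolute amplitude one.
#'
#' @param raw a [time_trace()], or a two-column data frame / matrix of
#'   `(time_s, value)` pairs for non-uniform recordings.
#' @param target_rate output sampling rate, Hz. Defaults to the input rate
#'   for a `time_trace`.
#' @param passband lowpass passband edge, Hz; must be below `target_rate / 2`.
#' @param invert flip the signal sign before normalization (for recordings
#'   with a negative-going R wave).
#' @return a [time_trace()] at `target_rate`, median 0, max |value| 1, with
#'   attribute `gaps` (data frame of interpolated gap start/length, possibly
#'   empty).
#' @export
preprocess_ecg <- function(raw, target_rate = NULL, passband = 100,
                           invert = FALSE) {
  if (inherits(raw, "time_trace")) {
    tt <- trace_times(raw)
    v <- raw$values
    if (is.null(target_rate)) target_rate <- raw$sampling_rate
  } else if ((is.data.frame(raw) || is.matrix(raw)) && ncol(raw) >= 2) {
    tt <- as.numeric(raw[[1]])
    v <- as.numeric(raw[[2]])
    if (is.null(target_rate))
      stop("`target_rate` is required for non-uniform input", call. = FALSE)
  } else {
    stop("`raw` must be a time_trace or a (time, value) table", call. = FALSE)
  }
  if (length(v) < 2L) stop("ECG trace too short to preprocess", call. = FALSE)
  if (passband >= target_rate / 2)
    stop("passband must be below the Nyquist frequency target_rate/2",
         call. = FALSE)
  if (max(v) - min(v) == 0)
    stop("degenerate (flat) signal: max - min is zero", call. = FALSE)

  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_rate)
  u <- stats::approx(tt, v, xout = grid, rule = 2)$y
  dt <- diff(tt)
  gap_idx <- which(dt > 2 / target_rate)
  gaps <- data.frame(start_s = tt[gap_idx], length_s = dt[gap_idx])

  bf <- signal::butter(4, passband / (target_rate / 2), type = "low")
  ## odd (point-symmetric) end reflection keeps filtfilt edge transients out
  npad <- min(length(u) - 1L, ceiling(target_rate / passband) * 8L)
  padded <- c(2 * u[1] - u[(npad + 1L):2L], u,
              2 * u[length(u)] - u[length(u) - seq_len(npad)])
  f <- signal::filtfilt(bf, padded)[npad + seq_along(u)]

  if (invert) f <- -f
  f <- f - stats::median(f)
  m <- max(abs(f))
  if (m == 0) stop("degenerate signal after filtering", call. = FALSE)
  out <- time_trace(f / m, target_rate, start_time = grid[1])
  attr(out, "gaps") <- gaps
  out
}

#' Binarize a laser TTL recording into a pulse train
#'
#' Thresholds the recorded laser command at
#' `min + threshold_fraction * (max - min)` and returns the rising and
#' falling crossing times, refined to sub-sample precision by linear
#' interpolation between the bracketing samples.
#'
#' @param ttl a [time_trace()] of the recorded laser command.
#' @param threshold_fraction fraction of the signal range used as the
#'   threshold; default 0.5.
#' @return a [pulse_train()]; empty when the signal never crosses the
#'   threshold.
#' @export
binarize_pulses <- function(ttl, threshold_fraction = 0.5) {
  stopifnot(inherits(ttl, "time_trace"))
  v <- ttl$values
  rng <- range(v)
  if (diff(rng) == 0) return(pulse_train())
  thr <- rng[1] + threshold_fraction * diff(rng)
  hi <- v >= thr
  d <- diff(hi)
  up <- which(d == 1L)    # last sample below, next at/above
  down <- which(d == -1L)
  tt <- trace_times(ttl)
  rising <- tt[up] + (thr - v[up]) / (v[up + 1L] - v[up]) *
    (tt[up + 1L] - tt[up])
  falling <- tt[down] + (thr - v[down]) / (v[down + 1L] - v[down]) *
    (tt[down + 1L] - tt[down])
  ## trim to complete pulses: drop a leading falling or trailing rising edge
  if (length(falling) && (!length(rising) || falling[1] < rising[1]))
    falling <- falling[-1L]
  if (length(rising) > length(falling))
    rising <- rising[seq_along(falling)]
  if (length(rising) != length(falling))
    stop("malformed TTL: rising/falling edges do not alternate", call. = FALSE)
  pulse_train(rising, falling)
}
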