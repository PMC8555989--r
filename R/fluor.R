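#' Mean fluorescence trace over a rectangular ROI
#'
#' Per-frame mean intensity inside a rectangular region of interest,
#' timestamped from the stack frame rate — the signal used to read out
#' calcium-indicator activity from, e.g., a ventricular region.
#'
#' @param stack a [frame_stack()].
#' @param roi rectangle `c(x0, x1, y0, y1)` in 0-based pixel coordinates,
#'   inclusive.
#' @return data frame of class `fluor_trace` with columns `time_s`,
#'   `intensity`; attribute `sampling_rate`.
#' @export
extract_roi_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), length(roi) == 4L)
  d <- dim(stack$frames)
  xs <- (roi[1]:roi[2]) + 1L
  ys <- (roi[3]:roi[4]) + 1L
  if (roi[1] > roi[2] || roi[3] > roi[4] ||
      min(xs) < 1L || max(xs) > d[2] || min(ys) < 1L || max(ys) > d[1])
    stop("ROI is empty or extends outside the frames", call. = FALSE)
  vals <- apply(stack$frames[ys, xs, , drop = FALSE], 3, mean)
  out <- data.frame(time_s = (seq_len(d[3]) - 1) / stack$frame_rate,
                    intensity = vals)
  class(out) <- c("fluor_trace", "data.frame")
  attr(out, "sampling_rate") <- stack$frame_rate
  out
}

#' Pacing-to-transient coupling of a fluorescence trace
#'
#' Detects calcium-transient onsets as upward crossings of
#' `detect_threshold * (max - min)` on a running-median-detrended trace,
#' matches each laser pulse to the first onset within `match_window` ms
#' after its rising edge, and reports the per-pulse latency and the
#' coupling fraction (matched pulses / total pulses). A coupling fraction
#' of 1 with constant latency is the signature of 1:1 optical pacing.
#'
#' @param trace a [time_trace()] or `fluor_trace` data frame
#'   (`time_s`, `intensity`).
#' @param pulses a [pulse_train()].
#' @param detect_threshold onset threshold as a fraction of the detrended
#'   trace range (default 0.2).
#' @param match_window how long after a rising edge an onset may follow to
#'   count as coupled, ms (default 200).
#' @param detrend_window running-median baseline window, s (default 1;
#'   set to 0 to subtract the global median instead).
#' @param min_sustain a crossing only counts as an onset when the detrended
#'   trace stays at threshold (by median) for this long, ms (default 20);
#'   debounces noise-induced crossings on transient-free traces.
#' @param onset_floor after a threshold crossing, the onset time is walked
#'   back to where the rising edge leaves the baseline (first sample below
#'   this fraction of the range; default 0.02), removing the rise-time bias
#'   a plain threshold crossing would add to the latency.
#' @return list with `latency_ms` (one value per pulse, `NA` if unmatched),
#'   `coupling_fraction`, `onset_times_s`.
#' @export
pacing_coupling <- function(trace, pulses, detect_threshold = 0.2,
                            match_window = 200, detrend_window = 1,
                            min_sustain = 20, onset_floor = 0.02) {
  stopifnot(inherits(pulses, "pulse_train"))
  if (inherits(trace, "time_trace")) {
    tt <- trace_times(trace); v <- trace$values
    fs <- trace$sampling_rate
  } else {
    tt <- trace$time_s; v <- trace$intensity
    fs <- 1 / stats::median(diff(tt))
  }
  if (max(v) - min(v) == 0)
    stop("zero-range trace: no transients detectable", call. = FALSE)

  if (detrend_window > 0) {
    k <- round(detrend_window * fs)
    if (k %% 2 == 0) k <- k + 1
    k <- max(3, min(k, length(v) - (1 - length(v) %% 2)))
    base <- stats::runmed(v, k)
  } else {
    base <- stats::median(v)
  }
  dv <- v - base
  thr <- detect_threshold * (max(dv) - min(dv))
  up <- which(dv[-1] >= thr & dv[-length(dv)] < thr) + 1L
  ks <- max(1L, round(min_sustain / 1000 * fs))
  sustained <- vapply(up, function(i) {
    stats::median(dv[i:min(length(dv), i + ks)]) >= thr
  }, logical(1))
  floor_lvl <- onset_floor * (max(dv) - min(dv))
  onsets <- vapply(up[sustained], function(i) {
    j <- i
    while (j > 1L && dv[j - 1L] > floor_lvl && dv[j - 1L] < dv[j]) j <- j - 1L
    ## the last at-baseline sample is the onset itself
    if (j > 1L && dv[j - 1L] <= floor_lvl) j <- j - 1L
    tt[j]
  }, numeric(1))

  n_p <- length(pulses$rising_edges)
  lat <- rep(NA_real_, n_p)
  for (i in seq_len(n_p)) {
    e <- pulses$rising_edges[i]
    cand <- onsets[onsets > e & onsets <= e + match_window / 1000]
    if (length(cand)) lat[i] <- (cand[1] - e) * 1000
  }
  list(latency_ms = lat,
       coupling_fraction = if (n_p) sum(!is.na(lat)) / n_p else NA_real_,
       onset_times_s = onsets)
}
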