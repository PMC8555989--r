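#' Uniformly sampled scalar signal
#'
#' Container for any uniformly sampled trace handled by the package: ECG
#' voltage, laser TTL command, respiratory pressure, or a fluorescence ROI
#' mean. Sample `i` (1-based) is taken at `start_time + (i - 1) / sampling_rate`
#' seconds.
#'
#' @param values numeric vector of samples (non-empty).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @return An object of class `time_trace`: a list with elements `values`,
#'   `sampling_rate`, `start_time`.
#' @examples
#' tr <- time_trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), 1000)
#' range(trace_times(tr))
#' @export
time_trace <- function(values, sampling_rate, start_time = 0) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(values = as.numeric(values),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time)),
    class = "time_trace"
  )
}

#' Sample times of a time_trace
#'
#' @param trace a [time_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  trace$start_time + (seq_along(trace$values) - 1) / trace$sampling_rate
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d samples @ %g Hz, t = [%.6g, %.6g] s\n",
              length(x$values), x$sampling_rate, x$start_time,
              x$start_time + (length(x$values) - 1) / x$sampling_rate))
  invisible(x)
}

#' @export
length.time_trace <- function(x) length(x$values)

#' Laser stimulation pulse train
#'
#' Rising and falling edge times of a binary (TTL) stimulation command.
#' Edges must strictly alternate rising < falling; a trailing rising edge
#' without its falling partner is not permitted.
#'
#' @param rising_edges sorted rising-edge times, seconds.
#' @param falling_edges sorted falling-edge times, seconds; same length as
#'   `rising_edges`, each falling edge after its rising edge.
#' @return An object of class `pulse_train` with elements `rising_edges`,
#'   `falling_edges` and, when non-empty, `pulse_length_ms` (mean duration).
#' @export
pulse_train <- function(rising_edges = numeric(0), falling_edges = numeric(0)) {
  rising_edges <- as.numeric(rising_edges)
  falling_edges <- as.numeric(falling_edges)
  if (length(rising_edges) != length(falling_edges))
    stop("rising and falling edge counts differ", call. = FALSE)
  if (is.unsorted(rising_edges, strictly = TRUE) ||
      is.unsorted(falling_edges, strictly = TRUE))
    stop("edge times must be strictly increasing", call. = FALSE)
  if (length(rising_edges) && any(falling_edges <= rising_edges))
    stop("each falling edge must follow its rising edge", call. = FALSE)
  if (length(rising_edges) > 1L &&
      any(rising_edges[-1L] <= falling_edges[-length(falling_edges)]))
    stop("pulses must not overlap: edges must alternate", call. = FALSE)
  structure(
    list(rising_edges = rising_edges,
         falling_edges = falling_edges,
         pulse_length_ms = if (length(rising_edges))
           mean(falling_edges - rising_edges) * 1000 else NA_real_),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses, mean length %.3f ms\n",
              length(x$rising_edges), x$pulse_length_ms))
  invisible(x)
}

#' Per-beat record table
#'
#' Canonical data frame of detected beats. One row per beat with the R-peak
#' time, the P-peak time (or `NA`), the classification label
#' (`"unstimulated"`, `"stimulated"`, or `"excluded"`), the measured R-wave
#' duration and PR interval in milliseconds (or `NA`), and the index of the
#' matched stimulation pulse for stimulated beats.
#'
#' @param r_peak_time_s strictly increasing R-peak times, seconds.
#' @param p_peak_time_s P-peak times, seconds (`NA` when not found).
#' @param label character labels; defaults to `"unstimulated"`.
#' @param r_duration_ms,pr_interval_ms measured intervals, ms (`NA` before
#'   measurement).
#' @param matched_pulse_index 1-based index into the pulse train, `NA` unless
#'   the beat is stimulated.
#' @return data frame of class `beat_table`.
#' @export
beat_table <- function(r_peak_time_s,
                       p_peak_time_s = rep(NA_real_, length(r_peak_time_s)),
                       label = rep("unstimulated", length(r_peak_time_s)),
                       r_duration_ms = rep(NA_real_, length(r_peak_time_s)),
                       pr_interval_ms = rep(NA_real_, length(r_peak_time_s)),
                       matched_pulse_index = rep(NA_integer_, length(r_peak_time_s))) {
  r_peak_time_s <- as.numeric(r_peak_time_s)
  if (length(r_peak_time_s) && is.unsorted(r_peak_time_s, strictly = TRUE))
    stop("r_peak_time_s must be strictly increasing", call. = FALSE)
  ok <- label %in% c("unstimulated", "stimulated", "excluded")
  if (!all(ok))
    stop("labels must be one of unstimulated/stimulated/excluded", call. = FALSE)
  out <- data.frame(
    r_peak_time_s = r_peak_time_s,
    p_peak_time_s = as.numeric(p_peak_time_s),
    label = as.character(label),
    r_duration_ms = as.numeric(r_duration_ms),
    pr_interval_ms = as.numeric(pr_interval_ms),
    matched_pulse_index = as.integer(matched_pulse_index),
    stringsAsFactors = FALSE
  )
  class(out) <- c("beat_table", "data.frame")
  out
}
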