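#' Generate a synthetic line-scan acquisition with cardiac modulation
#'
#' Emulates a resonant-scanned fluorescence acquisition of beating tissue:
#' frames of `n_lines_per_frame` rows are scanned top to bottom at
#' `frame_rate`, each line carrying its own acquisition timestamp. Line
#' intensity is `base(row, col) * (1 + modulation_depth * s(phase))` where
#' `s(phase) = sin(2 * pi * phase)` and the cardiac phase advances with
#' period `cardiac_period` (phase 0 at each simulated R peak). A simulated
#' ECG trace with R peaks at multiples of `cardiac_period` and a sinusoidal
#' respiration trace (peaks at multiples of `resp_period`) are returned
#' alongside.
#'
#' @param n_lines_per_frame rows per frame.
#' @param frame_rate frames per second.
#' @param cardiac_period simulated RR interval, s (must be shorter than
#'   `resp_period`).
#' @param resp_period simulated respiratory period, s.
#' @param modulation_depth fractional cardiac intensity modulation, in
#'   `[0, 1)`.
#' @param n_frames number of frames scanned.
#' @param n_cols pixels per line.
#' @param noise_sd additive white-noise SD, a.u.
#' @param seed integer RNG seed.
#' @return list with elements
#'   \describe{
#'     \item{lines}{`line_record_set`: list with `pixels` (matrix, one line
#'       per row), `acquisition_time_s`, `row_index` (0-based),
#'       `rows_per_frame`, `n_cols`.}
#'     \item{ecg}{[time_trace()] with a spike at each simulated R peak.}
#'     \item{resp}{[time_trace()] of the respiration signal.}
#'     \item{truth}{list: `phase_per_line`, `r_peaks_s`, `resp_peaks_s`,
#'       `base_image`, `modulation` (the function `s`), `seed`.}
#'   }
#' @export
synth_linescan <- function(n_lines_per_frame = 64, frame_rate = 30,
                           cardiac_period = 0.12, resp_period = 0.63,
                           modulation_depth = 0.3, n_frames = 60,
                           n_cols = 32, noise_sd = 0, seed = 1) {
  if (cardiac_period >= resp_period)
    stop("cardiac_period must be shorter than resp_period", call. = FALSE)
  if (modulation_depth < 0 || modulation_depth >= 1)
    stop("modulation_depth must be in [0, 1)", call. = FALSE)
  local_seed(seed)

  rows <- rep(0:(n_lines_per_frame - 1L), times = n_frames)
  frames <- rep(0:(n_frames - 1L), each = n_lines_per_frame)
  line_dt <- 1 / (frame_rate * n_lines_per_frame)
  t_line <- frames / frame_rate + rows * line_dt
  duration <- n_frames / frame_rate

  r_peaks <- seq(0, duration + cardiac_period, by = cardiac_period)
  phase <- (t_line %% cardiac_period) / cardiac_period
  s_fun <- function(phi) sin(2 * pi * phi)

  ## smooth deterministic base image
  rr <- 0:(n_lines_per_frame - 1L)
  cc <- 0:(n_cols - 1L)
  base <- 50 + 30 * outer(sin(2 * pi * rr / n_lines_per_frame),
                          cos(2 * pi * cc / n_cols)) +
    10 * outer(cos(4 * pi * rr / n_lines_per_frame), rep(1, n_cols))

  gain <- 1 + modulation_depth * s_fun(phase)
  pix <- base[rows + 1L, , drop = FALSE] * gain
  if (noise_sd > 0)
    pix <- pix + matrix(stats::rnorm(length(pix), 0, noise_sd),
                        nrow = nrow(pix))

  lines <- structure(
    list(pixels = pix, acquisition_time_s = t_line, row_index = rows,
         rows_per_frame = as.integer(n_lines_per_frame),
         n_cols = as.integer(n_cols)),
    class = "line_record_set")

  fs <- 1000
  tg <- seq(0, duration, by = 1 / fs)
  ecg_v <- numeric(length(tg))
  for (rp in r_peaks) {                       # narrow triangular R spikes
    idx <- which(abs(tg - rp) < 0.004)
    ecg_v[idx] <- pmax(ecg_v[idx], 1 - abs(tg[idx] - rp) / 0.004)
  }
  resp_peaks <- seq(0, duration + resp_period, by = resp_period)
  resp_v <- cos(2 * pi * tg / resp_period)

  list(lines = lines,
       ecg = time_trace(ecg_v, fs),
       resp = time_trace(resp_v, fs),
       truth = list(phase_per_line = phase, r_peaks_s = r_peaks,
                    resp_peaks_s = resp_peaks, base_image = base,
                    modulation = s_fun, seed = as.integer(seed)))
}

#' @export
print.line_record_set <- function(x, ...) {
  cat(sprintf("<line_record_set> %d lines (%d rows/frame, %d cols)\n",
              nrow(x$pixels), x$rows_per_frame, x$n_cols))
  invisible(x)
}

#' Generate a synthetic calcium-indicator trace locked to pacing pulses
#'
#' One double-exponential transient,
#' `amplitude * (1 - exp(-tau/rise)) * exp(-tau/decay)`, begins `latency`
#' ms after every pulse rising edge (`tau` = time since onset).
#' Overlapping transients sum. The baseline is constant zero plus optional
#' white noise.
#'
#' @param pulses a [pulse_train()].
#' @param latency transient onset delay after the pulse rising edge, ms.
#' @param rise,decay kernel time constants, ms (> 0).
#' @param amplitude kernel scale, a.u.
#' @param noise_sd additive white-noise SD, a.u.
#' @param sampling_rate Hz.
#' @param duration trace length, s; defaults to the last pulse plus
#'   `latency` plus ten decay constants.
#' @param seed integer RNG seed.
#' @return list with `trace` (a [time_trace()]) and `truth` (list:
#'   `onset_times_s`, `kernel` function of `tau` seconds, `seed`).
#' @export
synth_fluor_trace <- function(pulses, latency = 50, rise = 10, decay = 100,
                              amplitude = 1, noise_sd = 0,
                              sampling_rate = 1000, duration = NULL,
                              seed = 1) {
  stopifnot(inherits(pulses, "pulse_train"))
  if (latency <= 0 || rise <= 0 || decay <= 0)
    stop("latency, rise, and decay must be positive (ms)", call. = FALSE)
  local_seed(seed)
  onsets <- pulses$rising_edges + latency / 1000
  if (is.null(duration))
    duration <- (if (length(onsets)) max(onsets) else 0) + 10 * decay / 1000
  n <- floor(duration * sampling_rate) + 1L
  t <- (seq_len(n) - 1) / sampling_rate
  kernel <- function(tau)
    ifelse(tau >= 0,
           amplitude * (1 - exp(-tau / (rise / 1000))) *
             exp(-tau / (decay / 1000)),
           0)
  v <- numeric(n)
  for (on in onsets) v <- v + kernel(t - on)
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  list(trace = time_trace(v, sampling_rate),
       truth = list(onset_times_s = onsets, kernel = kernel,
                    seed = as.integer(seed)))
}
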