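#' Detect R-wave peaks in a preprocessed ECG
#'
#' Finds local maxima exceeding `min_height` (in normalized amplitude units)
#' separated by at least `min_separation` ms, using the MATLAB-style peak
#' finder [pracma::findpeaks()]. Peak times are reported at the nearest
#' sample; no sub-sample refinement is applied, matching how the intervals
#' downstream are anchored.
#'
#' Automated detection is expected to be followed by manual curation; see
#' [write_peaks()] / [read_peaks()] for the CSV round-trip used to edit a
#' peak list by hand.
#'
#' @param ecg a [time_trace()], normally from [preprocess_ecg()].
#' @param min_height minimum peak height, normalized units (default 0.4).
#' @param min_separation minimum peak spacing, ms (default 50).
#' @return sorted numeric vector of R-peak times, seconds (possibly empty).
#' @export
detect_r_peaks <- function(ecg, min_height = 0.4, min_separation = 50) {
  stopifnot(inherits(ecg, "time_trace"))
  v <- ecg$values
  if (all(v <= min_height)) return(numeric(0))
  mpd <- max(1L, round(min_separation / 1000 * ecg$sampling_rate))
  pk <- pracma::findpeaks(v, minpeakheight = min_height,
                          minpeakdistance = mpd)
  if (is.null(pk)) return(numeric(0))
  sort(trace_times(ecg)[pk[, 2L]])
}

#' Detect P-wave peaks preceding each R peak
#'
#' For each R peak, takes the maximum sample in the window
#' `[r - search_window, r - guard]` ms. The guard interval keeps the QRS
#' upstroke out of the search. A beat's P wave is reported missing (`NA`)
#' when the window extends before the trace start or when the candidate's
#' prominence above the window median is below `min_prominence` (flat or
#' noise-only segment).
#'
#' @param ecg a preprocessed [time_trace()].
#' @param r_peaks sorted R-peak times, seconds.
#' @param search_window how far before the R peak to search, ms (default 100).
#' @param guard blanking interval immediately before the R peak, ms
#'   (default 10).
#' @param min_prominence minimum height of the P candidate above the window
#'   median, normalized units (default 0.1).
#' @return numeric vector, one P-peak time (s) or `NA` per R peak.
#' @export
detect_p_waves <- function(ecg, r_peaks, search_window = 100, guard = 10,
                           min_prominence = 0.1) {
  stopifnot(inherits(ecg, "time_trace"))
  if (is.unsorted(r_peaks)) stop("r_peaks must be sorted", call. = FALSE)
  tt <- trace_times(ecg)
  fs <- ecg$sampling_rate
  vapply(r_peaks, function(r) {
    lo <- r - search_window / 1000
    hi <- r - guard / 1000
    if (lo < tt[1] || hi <= lo) return(NA_real_)
    i0 <- max(1L, ceiling((lo - ecg$start_time) * fs) + 1L)
    i1 <- min(length(ecg$values), floor((hi - ecg$start_time) * fs) + 1L)
    if (i1 - i0 < 2L) return(NA_real_)
    w <- ecg$values[i0:i1]
    j <- which.max(w)
    if (w[j] - stats::median(w) < min_prominence) return(NA_real_)
    tt[i0 + j - 1L]
  }, numeric(1))
}
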