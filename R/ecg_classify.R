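#' Classify beats by stimulus latency windows
#'
#' Labels every beat as `unstimulated`, `stimulated`, or `excluded` using
#' the capture criteria for optically paced hearts:
#' \itemize{
#'   \item \emph{unstimulated} — the R peak precedes the first laser pulse
#'     rising edge (autonomous rhythm before stimulation onset);
#'   \item \emph{stimulated}, ventricular mode — the R peak falls 10-38 ms
#'     (inclusive) after the nearest preceding pulse \emph{rising} edge;
#'   \item \emph{stimulated}, nodal mode — the P peak falls 38-52 ms
#'     (inclusive) after the nearest preceding pulse \emph{falling} edge;
#'   \item \emph{excluded} — any other beat occurring after stimulation
#'     onset (including nodal-mode beats with no detected P wave).
#' }
#' Each pulse captures at most one beat: when two beats qualify against the
#' same pulse, only the earlier one is labeled stimulated and later ones are
#' excluded. Window bounds are inclusive, compared with a 1 ns numerical
#' tolerance.
#'
#' @param beats a [beat_table()] (labels are overwritten).
#' @param pulses a [pulse_train()] on the same clock as `beats`.
#' @param mode `"ventricular"` or `"nodal"`.
#' @param window latency window in ms; defaults to `c(10, 38)` for
#'   ventricular mode and `c(38, 52)` for nodal mode.
#' @return the beat table with `label` and `matched_pulse_index` filled in.
#' @export
classify_beats <- function(beats, pulses,
                           mode = c("ventricular", "nodal"),
                           window = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(beats, "beat_table"), inherits(pulses, "pulse_train"))
  if (is.null(window))
    window <- if (mode == "ventricular") c(10, 38) else c(38, 52)
  w <- window / 1000
  eps <- 1e-9

  n <- nrow(beats)
  beats$label <- rep("excluded", n)
  beats$matched_pulse_index <- rep(NA_integer_, n)
  if (n == 0L) return(beats)

  if (length(pulses$rising_edges) == 0L) {
    beats$label[] <- "unstimulated"
    return(beats)
  }
  onset <- pulses$rising_edges[1]
  pre <- beats$r_peak_time_s < onset
  beats$label[pre] <- "unstimulated"

  edges <- if (mode == "ventricular") pulses$rising_edges
           else pulses$falling_edges
  ref <- if (mode == "ventricular") beats$r_peak_time_s
         else beats$p_peak_time_s

  taken <- rep(FALSE, length(edges))
  for (i in which(!pre)) {
    if (is.na(ref[i])) next                      # e.g. missing P wave: excluded
    j <- findInterval(ref[i] + eps, edges)       # nearest preceding edge
    if (j < 1L) next
    lat <- ref[i] - edges[j]
    if (lat >= w[1] - eps && lat <= w[2] + eps && !taken[j]) {
      beats$label[i] <- "stimulated"
      beats$matched_pulse_index[i] <- j
      taken[j] <- TRUE
    }
  }
  beats
}
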