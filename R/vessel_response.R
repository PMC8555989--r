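#' Running-average smoothing of a diameter trace
#'
#' Centered moving mean over `window` frames applied to the width series
#' before response metrics are computed. Missing widths (failed frames) are
#' skipped; near the trace edges the mean is taken over the valid
#' neighbors only, so the output has the same length as the input.
#'
#' @param trace a `diameter_trace` from [diameter_series()], or a numeric
#'   width vector.
#' @param window odd window length in frames, >= 1 (default 5).
#' @return same type as the input with the width series smoothed.
#' @export
smooth_running_average <- function(trace, window = 5) {
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be odd and >= 1", call. = FALSE)
  w <- if (is.data.frame(trace)) trace$width_um else as.numeric(trace)
  if (window > length(w))
    stop("`window` exceeds the series length", call. = FALSE)
  if (window == 1L) return(trace)
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_along(w), function(i) {
    idx <- max(1L, i - h):min(length(w), i + h)
    vals <- w[idx]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (is.data.frame(trace)) {
    trace$width_um <- sm
    trace
  } else sm
}

#' Opto-stimulation response metrics of a vessel width trace
#'
#' Quantifies the vessel response to laser activation. For a dilation, the
#' reference is the minimum smoothed width in the first `min_search`
#' seconds after laser onset (MIN), the response the maximum width during
#' activation `[laser_on, laser_off]` (MAX), and the percent change
#' `((MAX - MIN) / MIN) * 100`; the net-change series is the width minus
#' MIN. For a constriction the roles of the extrema swap: the reference is
#' the maximum in the first window and the response the minimum during
#' activation, giving a negative percent change.
#'
#' @param trace a (smoothed) `diameter_trace`.
#' @param laser_on,laser_off laser activation epoch, s (`laser_on <
#'   laser_off`).
#' @param min_search length of the post-onset window searched for the
#'   reference extremum, s (default 10).
#' @param direction `"dilation"` (default) or `"constriction"`.
#' @return list of class `response_metrics`: `min_width_um`,
#'   `max_width_um`, `pct_change`, `net_change_um` (per-frame series),
#'   `time_s`, `direction`.
#' @export
response_metrics <- function(trace, laser_on, laser_off, min_search = 10,
                             direction = c("dilation", "constriction")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(trace))
  if (!is.finite(laser_on) || !is.finite(laser_off) || laser_on >= laser_off)
    stop("need laser_on < laser_off", call. = FALSE)
  tt <- trace$time_s
  w <- trace$width_um
  if (max(tt) < laser_on + min_search)
    stop("trace does not cover the reference search window", call. = FALSE)
  ref_win <- tt >= laser_on & tt <= laser_on + min_search & !is.na(w)
  act_win <- tt >= laser_on & tt <= laser_off & !is.na(w)
  if (!any(ref_win) || !any(act_win))
    stop("no valid width samples in the search window", call. = FALSE)

  if (direction == "dilation") {
    min_w <- min(w[ref_win])
    max_w <- max(w[act_win])
    pct <- (max_w - min_w) / min_w * 100
    net <- w - min_w
  } else {
    max_w <- max(w[ref_win])
    min_w <- min(w[act_win])
    pct <- (min_w - max_w) / max_w * 100
    net <- w - max_w
  }
  structure(list(min_width_um = min_w, max_width_um = max_w,
                 pct_change = pct, net_change_um = net, time_s = tt,
                 direction = direction),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf("<response_metrics> %s: MIN %.2f um, MAX %.2f um, %%change %.2f\n",
              x$direction, x$min_width_um, x$max_width_um, x$pct_change))
  invisible(x)
}
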