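#' Stabilize a frame stack by translation registration
#'
#' Removes inter-frame motion artifacts before vessel measurement. Every
#' frame is translated by the integer shift that maximizes its normalized
#' cross-correlation (on mean-subtracted pixels) with the first frame. When
#' the stack carries an `exclusion` rectangle — the area contaminated by
#' light leakage from the stimulation laser — the correlation is evaluated
#' only over its complement, so the registration locks onto tissue
#' structure rather than the beam.
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param search_radius maximum shift searched in each axis, px (default 20).
#' @return list with elements `stack` (the stabilized [frame_stack()],
#'   vacated borders zero-filled) and `shifts` (data frame `dx`, `dy`: the
#'   detected motion of each frame relative to frame 1).
#' @export
stabilize_stack <- function(stack, search_radius = 20) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  if (nf < 2L) stop("need at least 2 frames to stabilize", call. = FALSE)
  d <- dim(stack$frames)
  ny <- d[1]; nx <- d[2]
  mask <- matrix(TRUE, ny, nx)
  if (!is.null(stack$exclusion)) {
    e <- round(stack$exclusion)
    xs <- max(0, e[1]):min(nx - 1, e[2])
    ys <- max(0, e[3]):min(ny - 1, e[4])
    mask[ys + 1L, xs + 1L] <- FALSE
  }
  if (!any(mask))
    stop("exclusion region covers the whole frame", call. = FALSE)

  ref <- stack$frames[, , 1]
  r <- as.integer(search_radius)
  ## correlate over the reference interior (a margin of one search radius)
  ## so every candidate shift compares the same reference pixels and
  ## zero-filled borders of previously translated frames cannot bias the fit
  xs <- (r + 1L):(nx - r)
  ys <- (r + 1L):(ny - r)
  if (length(xs) < 4L || length(ys) < 4L)
    stop("search_radius too large for the frame size", call. = FALSE)
  m <- mask[ys, xs]
  if (sum(m) < 16L)
    stop("exclusion region leaves too few pixels for registration",
         call. = FALSE)
  a <- ref[ys, xs][m]
  if (stats::sd(a) == 0)
    stop("reference frame is flat inside the registration region",
         call. = FALSE)
  cand <- expand.grid(dx = -r:r, dy = -r:r)
  cand <- cand[order(abs(cand$dx) + abs(cand$dy)), ]  # prefer small shifts

  shifts <- data.frame(dx = integer(nf), dy = integer(nf))
  out <- stack$frames
  for (k in 2:nf) {
    fr <- stack$frames[, , k]
    best <- -Inf; bdx <- 0L; bdy <- 0L
    for (i in seq_len(nrow(cand))) {
      dx <- cand$dx[i]; dy <- cand$dy[i]
      b <- fr[ys + dy, xs + dx][m]
      if (stats::sd(b) == 0) next
      cc <- stats::cor(a, b)
      if (cc > best + 1e-12) { best <- cc; bdx <- dx; bdy <- dy }
    }
    shifts$dx[k] <- bdx; shifts$dy[k] <- bdy
    out[, , k] <- translate_frame(fr, -bdx, -bdy)
  }
  stabilized <- frame_stack(out, stack$frame_rate, stack$pixel_size,
                            stack$exclusion)
  list(stack = stabilized, shifts = shifts)
}

## integer translation with zero fill: out[y, x] = frame[y - dy, x - dx]
translate_frame <- function(frame, dx, dy) {
  ny <- nrow(frame); nx <- ncol(frame)
  out <- matrix(0, ny, nx)
  xs <- max(1L, 1L + dx):min(nx, nx + dx)
  ys <- max(1L, 1L + dy):min(ny, ny + dy)
  if (length(xs) && length(ys))
    out[ys, xs] <- frame[ys - dy, xs - dx]
  out
}

#' Band-averaged intensity profile along a measurement line
#'
#' Samples a frame's intensity along a user-specified line by bilinear
#' interpolation at steps of half a pixel, averaging at each position
#' across a perpendicular band of total width `band_width` um to suppress
#' noise. The number of band samples is `band_width / pixel_size` rounded
#' to the nearest odd integer, spaced one pixel apart and centered on the
#' line.
#'
#' @param frame 2-D intensity matrix.
#' @param line two endpoints as `list(c(x0, y0), c(x1, y1))` or a 2x2 matrix
#'   (rows = endpoints), 0-based pixel coordinates.
#' @param pixel_size um/px.
#' @param band_width total averaging band width, um (default 28.05).
#' @param step_um sampling step along the line, um; defaults to
#'   `pixel_size / 2`.
#' @return data frame of class `line_profile` with columns `position_um`
#'   (distance from the first endpoint) and `intensity`.
#' @export
extract_profile <- function(frame, line, pixel_size, band_width = 28.05,
                            step_um = NULL) {
  if (is.list(line)) line <- rbind(line[[1]], line[[2]])
  stopifnot(is.matrix(line), all(dim(line) == c(2, 2)))
  if (all(line[1, ] == line[2, ]))
    stop("line endpoints must be distinct", call. = FALSE)
  if (is.null(step_um)) step_um <- pixel_size / 2

  p0 <- line[1, ] * pixel_size          # um coordinates
  p1 <- line[2, ] * pixel_size
  len <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / len                  # unit vector along the line
  v <- c(-u[2], u[1])                   # unit perpendicular

  n_band <- max(1L, round(band_width / pixel_size))
  if (n_band %% 2L == 0L) n_band <- n_band + 1L
  offsets <- (seq_len(n_band) - (n_band + 1L) / 2) * pixel_size

  s <- seq(0, len, by = step_um)
  acc <- numeric(length(s))
  for (o in offsets) {
    px <- (p0[1] + s * u[1] + o * v[1]) / pixel_size
    py <- (p0[2] + s * u[2] + o * v[2]) / pixel_size
    acc <- acc + bilinear_sample(frame, px, py, band_offset_um = o)
  }
  out <- data.frame(position_um = s, intensity = acc / n_band)
  class(out) <- c("line_profile", "data.frame")
  attr(out, "n_band") <- n_band
  out
}

## Vectorized bilinear interpolation at 0-based pixel coordinates (x, y).
## Errors when any sample falls outside the frame.
bilinear_sample <- function(frame, x, y, band_offset_um = NULL) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (any(x < 0 | x > nx - 1 | y < 0 | y > ny - 1)) {
    where <- if (!is.null(band_offset_um))
      sprintf(" (band offset %.2f um)", band_offset_um) else ""
    bad <- which(x < 0 | x > nx - 1 | y < 0 | y > ny - 1)[1]
    stop(sprintf(
      "profile sample at (%.2f, %.2f) px falls outside the %d x %d frame%s",
      x[bad], y[bad], nx, ny, where), call. = FALSE)
  }
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  frame[i00] * (1 - fx) * (1 - fy) + frame[i01] * fx * (1 - fy) +
    frame[i10] * (1 - fx) * fy + frame[i11] * fx * fy
}

#' Locate the two vessel sidewalls in an intensity profile
#'
#' Selects the two most prominent local maxima of the profile (prominence,
#' not raw height, so lumen glare between the walls is not mistaken for a
#' wall) and refines each by a quadratic fit over `fit_window` samples
#' around the peak, giving sub-sample wall positions and intensities.
#'
#' @param profile a `line_profile` from [extract_profile()], or a data
#'   frame with columns `position_um` and `intensity`.
#' @param fit_window number of samples in the quadratic refinement window
#'   (odd, >= 3; default 3).
#' @return list with `left_um`, `right_um`, `left_intensity`,
#'   `right_intensity`, `width_um`.
#' @export
detect_walls <- function(profile, fit_window = 3) {
  pos <- profile$position_um
  y <- profile$intensity
  n <- length(y)
  if (n < 5L) stop("profile too short (need >= 5 samples)", call. = FALSE)
  if (fit_window < 3L || fit_window %% 2L == 0L)
    stop("fit_window must be odd and >= 3", call. = FALSE)

  peaks <- local_maxima(y)
  if (length(peaks) < 2L)
    stop("two walls not found: fewer than two local maxima in the profile",
         call. = FALSE)
  prom <- peak_prominence(y, peaks)
  keep <- peaks[order(prom, decreasing = TRUE)[1:2]]
  keep <- sort(keep)

  refine <- function(i) {
    h <- (fit_window - 1L) %/% 2L
    lo <- max(1L, i - h); hi <- min(n, i + h)
    xs <- pos[lo:hi]; ys <- y[lo:hi]
    co <- unname(stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients)
    a <- co[1]; b <- co[2]; cc <- co[3]
    if (!is.finite(cc) || cc >= 0)      # degenerate: keep the sample peak
      return(c(pos[i], y[i]))
    xv <- -b / (2 * cc)
    if (xv < xs[1] || xv > xs[length(xs)])  # vertex escaped the window
      return(c(pos[i], y[i]))
    c(xv, a - b^2 / (4 * cc))
  }
  L <- refine(keep[1]); R <- refine(keep[2])
  list(left_um = L[1], right_um = R[1],
       left_intensity = L[2], right_intensity = R[2],
       width_um = R[1] - L[1])
}

## indices of strict local maxima (first of any plateau)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

## topographic prominence of each peak index
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    h <- y[i]
    left <- if (i > 1L) {
      higher <- which(y[1:(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(i - 1L)])
    } else h
    right <- if (i < length(y)) {
      higher <- which(y[(i + 1L):length(y)] > h)
      hi <- if (length(higher)) i + min(higher) - 1L else length(y)
      min(y[(i + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Vessel width and sidewall intensity per frame
#'
#' Runs [extract_profile()] and [detect_walls()] on every frame of a
#' (stabilized) stack, producing the width and sidewall-intensity time
#' series. Frames where wall detection fails carry `NA` and are reported in
#' the `failed_frames` attribute; the run aborts if more than half the
#' frames fail.
#'
#' @param stack a stabilized [frame_stack()].
#' @param line measurement line (see [extract_profile()]).
#' @param band_width averaging band, um (default 28.05).
#' @param fit_window quadratic refinement window (default 3).
#' @return data frame of class `diameter_trace`: `time_s`, `width_um`,
#'   `left_um`, `right_um`, `left_intensity`, `right_intensity`. Attributes
#'   `frame_rate`, `pixel_size`, `failed_frames`.
#' @export
diameter_series <- function(stack, line, band_width = 28.05, fit_window = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  rows <- vector("list", nf)
  failed <- integer(0)
  for (k in seq_len(nf)) {
    res <- tryCatch({
      pr <- extract_profile(stack$frames[, , k], line, stack$pixel_size,
                            band_width = band_width)
      detect_walls(pr, fit_window = fit_window)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, k)
      rows[[k]] <- c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      rows[[k]] <- c(res$width_um, res$left_um, res$right_um,
                     res$left_intensity, res$right_intensity)
    }
  }
  if (length(failed) > nf / 2)
    stop(sprintf("wall detection failed on %d of %d frames",
                 length(failed), nf), call. = FALSE)
  m <- do.call(rbind, rows)
  out <- data.frame(time_s = (seq_len(nf) - 1) / stack$frame_rate,
                    width_um = m[, 1], left_um = m[, 2], right_um = m[, 3],
                    left_intensity = m[, 4], right_intensity = m[, 5])
  class(out) <- c("diameter_trace", "data.frame")
  attr(out, "frame_rate") <- stack$frame_rate
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "failed_frames") <- failed
  out
}
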