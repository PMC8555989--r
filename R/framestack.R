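#' Image stack container
#'
#' A stack of equally sized grayscale frames with acquisition metadata.
#' Pixel coordinates are 0-based throughout the package: pixel `(x, y)`
#' refers to column `x + 1`, row `y + 1` of the frame matrix.
#'
#' @param frames 3-D numeric array `[ny, nx, n_frames]`, or a list of
#'   equally sized matrices.
#' @param frame_rate frames per second.
#' @param pixel_size microns per pixel.
#' @param exclusion optional rectangle `c(x0, x1, y0, y1)` (0-based pixel
#'   bounds, inclusive) that the stabilizer must ignore — the image area
#'   affected by light leakage from the stimulation laser.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, pixel_size, exclusion = NULL) {
  if (is.list(frames)) {
    shp <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
      stop("all frames must have the same shape", call. = FALSE)
    frames <- array(unlist(frames), dim = c(shp, length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an [ny, nx, n] array or list of matrices",
         call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (um/px)", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("`frame_rate` must be positive (Hz)", call. = FALSE)
  if (!is.null(exclusion)) {
    if (length(exclusion) != 4L)
      stop("`exclusion` must be c(x0, x1, y0, y1)", call. = FALSE)
    if (exclusion[1] <= 0 && exclusion[2] >= dim(frames)[2] - 1 &&
        exclusion[3] <= 0 && exclusion[4] >= dim(frames)[1] - 1)
      stop("exclusion region covers the whole frame", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size, exclusion = exclusion),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g Hz, %g um/px\n",
              d[3], d[2], d[1], x$frame_rate, x$pixel_size))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]
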