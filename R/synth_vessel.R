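#' Specification for the synthetic vessel video generator
#'
#' Parameters of [synth_vessel_video()]. The synthetic vessel runs
#' horizontally across the frame: its two sidewalls are bright Gaussian
#' ridges (SD `wall_profile_sd` um) whose vertical separation follows the
#' commanded `width_timecourse`. Each frame is translated by an integer
#' jitter drawn uniformly from `[-jitter_max, jitter_max]` px in x and y,
#' and a fixed smooth random background texture moves with the jitter so
#' that frame registration has structure to lock onto.
#'
#' @param frame_rate Hz.
#' @param n_frames number of frames.
#' @param pixel_size um/px.
#' @param image_shape `c(ny, nx)` pixels.
#' @param baseline_width resting vessel width, um.
#' @param width_timecourse `NULL` (constant `baseline_width`), a numeric
#'   vector of per-frame widths (um), or a `function(t_seconds)` returning
#'   the width.
#' @param wall_profile_sd Gaussian ridge SD, um; must satisfy
#'   `baseline_width > 4 * wall_profile_sd`.
#' @param wall_intensity ridge peak intensity, a.u.
#' @param background constant background level, a.u.
#' @param texture_amplitude amplitude of the smooth random background
#'   texture, a.u.
#' @param noise_sd additive white-noise SD, a.u.
#' @param jitter_max maximum per-frame translation, px (integer; 0 = none).
#' @param laser_on,laser_off stimulation epoch, s (metadata copied to the
#'   ground truth; the commanded widths are whatever `width_timecourse`
#'   says).
#' @param seed integer RNG seed.
#' @return list of class `vessel_sim_spec`.
#' @export
vessel_sim_spec <- function(frame_rate = 10, n_frames = 100, pixel_size = 0.55,
                            image_shape = c(160, 120), baseline_width = 50,
                            width_timecourse = NULL, wall_profile_sd = 3,
                            wall_intensity = 100, background = 20,
                            texture_amplitude = 10, noise_sd = 0,
                            jitter_max = 0, laser_on = NA_real_,
                            laser_off = NA_real_, seed = 1) {
  if (baseline_width <= 4 * wall_profile_sd)
    stop("baseline_width must exceed 4 * wall_profile_sd", call. = FALSE)
  if (any(c(frame_rate, n_frames, pixel_size, baseline_width,
            wall_profile_sd) <= 0))
    stop("rates, sizes, and widths must be positive", call. = FALSE)
  spec <- list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
               pixel_size = pixel_size, image_shape = as.integer(image_shape),
               baseline_width = baseline_width,
               width_timecourse = width_timecourse,
               wall_profile_sd = wall_profile_sd,
               wall_intensity = wall_intensity, background = background,
               texture_amplitude = texture_amplitude, noise_sd = noise_sd,
               jitter_max = as.integer(jitter_max),
               laser_on = laser_on, laser_off = laser_off,
               seed = as.integer(seed))
  class(spec) <- "vessel_sim_spec"
  spec
}

#' Generate a synthetic vessel video with ground truth
#'
#' Renders the frame stack described by a [vessel_sim_spec()] and records
#' the commanded per-frame width and the applied per-frame jitter as ground
#' truth. The vessel midline sits at the vertical center of the unshifted
#' frame; wall positions along a vertical measurement line are therefore
#' `center +/- width/2` um.
#'
#' @param spec a [vessel_sim_spec()].
#' @return list with elements
#'   \describe{
#'     \item{stack}{[frame_stack()] of rendered frames.}
#'     \item{truth}{list: `width_per_frame_um`, `shift_per_frame` (data
#'       frame `dx`, `dy` px), `center_um` (vessel midline position along a
#'       vertical line, um from row 0), `time_s`, `seed`, `spec`.}
#'   }
#' @export
synth_vessel_video <- function(spec) {
  stopifnot(inherits(spec, "vessel_sim_spec"))
  local_seed(spec$seed)
  ny <- spec$image_shape[1]; nx <- spec$image_shape[2]
  tvec <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
  w <- spec$width_timecourse
  widths <- if (is.null(w)) rep(spec$baseline_width, spec$n_frames)
            else if (is.function(w)) vapply(tvec, w, numeric(1))
            else rep_len(as.numeric(w), spec$n_frames)
  if (any(widths <= 0)) stop("commanded widths must be positive", call. = FALSE)
  fov_um <- ny * spec$pixel_size
  if (any(widths + 8 * spec$wall_profile_sd > fov_um))
    stop("commanded width exceeds the field of view", call. = FALSE)

  jm <- spec$jitter_max
  dx <- if (jm > 0) sample(-jm:jm, spec$n_frames, replace = TRUE) else
    rep(0L, spec$n_frames)
  dy <- if (jm > 0) sample(-jm:jm, spec$n_frames, replace = TRUE) else
    rep(0L, spec$n_frames)
  dx[1] <- dy[1] <- 0L   # reference frame is unshifted

  ## fixed smooth background texture on an enlarged canvas, cropped per
  ## frame at the jitter offset so it translates rigidly with the scene
  pad <- jm
  tex <- matrix(0, ny + 2 * pad, nx + 2 * pad)
  if (spec$texture_amplitude > 0) {
    ## dense granular texture (many small Gaussian speckles) so that
    ## registration has structure everywhere, as real tissue does
    xg <- seq_len(nx + 2 * pad); yg <- seq_len(ny + 2 * pad)
    n_blob <- max(40L, round(length(tex) / 150))
    cxs <- stats::runif(n_blob, 1, nx + 2 * pad)
    cys <- stats::runif(n_blob, 1, ny + 2 * pad)
    sds <- stats::runif(n_blob, 2, 8)
    amps <- stats::rnorm(n_blob, 0, spec$texture_amplitude)
    for (b in seq_len(n_blob)) {
      tex <- tex + amps[b] * outer(exp(-0.5 * ((yg - cys[b]) / sds[b])^2),
                                   exp(-0.5 * ((xg - cxs[b]) / sds[b])^2))
    }
  }

  cy_px <- (ny - 1) / 2                 # vessel midline row (0-based)
  sd_px <- spec$wall_profile_sd / spec$pixel_size
  rows0 <- 0:(ny - 1)
  frames <- array(0, dim = c(ny, nx, spec$n_frames))
  for (k in seq_len(spec$n_frames)) {
    half_px <- widths[k] / 2 / spec$pixel_size
    y1 <- cy_px - half_px + dy[k]
    y2 <- cy_px + half_px + dy[k]
    ridge <- spec$wall_intensity * (exp(-0.5 * ((rows0 - y1) / sd_px)^2) +
                                    exp(-0.5 * ((rows0 - y2) / sd_px)^2))
    ## texture crop: scene shifted by (+dx, +dy) means sampling the canvas
    ## at an offset of -d relative to center
    fr <- spec$background +
      tex[(pad - dy[k]) + seq_len(ny), (pad - dx[k]) + seq_len(nx)] +
      matrix(ridge, ny, nx)
    if (spec$noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
    frames[, , k] <- fr
  }
  ## mark the vessel band (its walls move with dilation, not with frame
  ## motion) as the stabilizer's exclusion region, mirroring how the area
  ## contaminated by the stimulation beam is excluded on real recordings
  band_px <- (max(widths) / 2 + 4 * spec$wall_profile_sd) / spec$pixel_size
  excl <- c(0, nx - 1,
            max(0, floor(cy_px - band_px - jm)),
            min(ny - 1, ceiling(cy_px + band_px + jm)))
  stack <- frame_stack(frames, spec$frame_rate, spec$pixel_size,
                       exclusion = excl)
  list(stack = stack,
       truth = list(width_per_frame_um = widths,
                    shift_per_frame = data.frame(dx = dx, dy = dy),
                    center_um = cy_px * spec$pixel_size,
                    time_s = tvec, seed = spec$seed, spec = spec))
}
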