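mk_textured_stack <- function(n = 3, ny = 80, nx = 100, seed = 1,
                              exclusion = NULL) {
  set.seed(seed)
  base <- matrix(0, ny + 40, nx + 40)
  for (b in 1:30) {
    cx <- runif(1, 1, nx + 40); cy <- runif(1, 1, ny + 40)
    s <- runif(1, 2, 8)
    base <- base + rnorm(1, 0, 10) *
      outer(exp(-0.5 * ((seq_len(ny + 40) - cy) / s)^2),
            exp(-0.5 * ((seq_len(nx + 40) - cx) / s)^2))
  }
  crop <- function(dx, dy) base[(20 - dy) + seq_len(ny), (20 - dx) + seq_len(nx)]
  list(base = base, crop = crop,
       stack = function(shifts) {
      frames <- lapply(seq_len(nrow(shifts)), function(k)
        crop(shifts$dx[k], shifts$dy[k]) +
          matrix(rnorm(ny * nx, 0, 0.5), ny, nx))
      frame_stack(frames, frame_rate = 10, pixel_size = 0.5,
                  exclusion = exclusion)
    })
}

test_that("identical frames stabilize with zero shifts", {
  f <- matrix(rnorm(80 * 100), 80, 100)
  st <- frame_stack(list(f, f, f), 10, 0.5)
  out <- stabilize_stack(st, search_radius = 5)
  expect_true(all(out$shifts == 0))
})

test_that("a known integer translation is recovered and equals the oracle", {
  h <- mk_textured_stack(seed = 2)
  shifts <- data.frame(dx = c(0, 3, -2), dy = c(0, -2, 4))
  st <- h$stack(shifts)
  out <- stabilize_stack(st, search_radius = 6)
  expect_equal(out$shifts$dx, shifts$dx)
  expect_equal(out$shifts$dy, shifts$dy)
  mask <- matrix(TRUE, 80, 100)
  for (k in 2:3) {
    oracle <- shift_search_oracle(st$frames[, , 1], st$frames[, , k],
                                  mask, 6)
    expect_equal(c(out$shifts$dx[k], out$shifts$dy[k]), oracle)
  }
})

test_that("stabilizing an already-stabilized stack yields zero shifts", {
  h <- mk_textured_stack(seed = 3)
  st <- h$stack(data.frame(dx = c(0, 4, -3), dy = c(0, 1, -5)))
  once <- stabilize_stack(st, search_radius = 6)
  twice <- stabilize_stack(once$stack, search_radius = 6)
  expect_true(all(twice$shifts == 0))
})

test_that("a bright moving blob inside the exclusion region is ignored", {
  excl <- c(30, 69, 20, 59)               # x0 x1 y0 y1, 0-based
  h <- mk_textured_stack(seed = 4, exclusion = excl)
  st <- h$stack(data.frame(dx = c(0, 0, 0), dy = c(0, 0, 0)))
  fr <- st$frames
  for (k in 2:3) {                         # blob walks inside the exclusion
    yy <- 30 + 5 * k; xx <- 40 + 5 * k
    fr[yy + (-3:3), xx + (-3:3), k] <- fr[yy + (-3:3), xx + (-3:3), k] + 200
  }
  st2 <- frame_stack(fr, 10, 0.5, exclusion = excl)
  out <- stabilize_stack(st2, search_radius = 6)
  expect_true(all(out$shifts == 0))
  mask <- matrix(TRUE, 80, 100)
  mask[excl[3]:excl[4] + 1, excl[1]:excl[2] + 1] <- FALSE
  oracle <- shift_search_oracle(st2$frames[, , 1], st2$frames[, , 2], mask, 6)
  expect_equal(oracle, c(0L, 0L))
})

test_that("an exclusion region covering the whole frame is rejected", {
  f <- matrix(rnorm(400), 20, 20)
  expect_error(frame_stack(list(f, f), 10, 0.5,
                           exclusion = c(0, 19, 0, 19)), "whole frame")
})

test_that("profiles are exact on constant and bilinear intensity fields", {
  const <- matrix(7, 60, 60)
  line <- rbind(c(10, 10), c(50, 45))
  pr <- extract_profile(const, line, pixel_size = 1, band_width = 5)
  expect_true(all(abs(pr$intensity - 7) < 1e-12))
  # bilinear field a + b x + c y + d x y is reproduced exactly
  x <- matrix(0:59, 60, 60, byrow = TRUE); y <- matrix(0:59, 60, 60)
  fld <- 2 + 0.5 * x - 0.25 * y + 0.01 * x * y
  pr2 <- extract_profile(fld, rbind(c(12, 30), c(48, 30)), pixel_size = 1,
                         band_width = 1)
  expected <- 2 + 0.5 * (12 + pr2$position_um) - 0.25 * 30 +
    0.01 * (12 + pr2$position_um) * 30
  expect_equal(pr2$intensity, expected, tolerance = 1e-10)
})

test_that("the 28.05 um band at 0.55 um/px averages 51 perpendicular samples", {
  frame <- matrix(rnorm(200 * 200), 200, 200)
  pr <- extract_profile(frame, rbind(c(100, 50), c(100, 150)),
                        pixel_size = 0.55, band_width = 28.05)
  expect_equal(attr(pr, "n_band"), 51L)
  # direct-summation oracle at one position
  p0 <- c(100, 50) * 0.55
  u <- c(0, 1); v <- c(-1, 0)
  s <- pr$position_um[10]
  offs <- (-25:25) * 0.55
  vals <- vapply(offs, function(o) {
    px <- (p0[1] + s * u[1] + o * v[1]) / 0.55
    py <- (p0[2] + s * u[2] + o * v[2]) / 0.55
    x0 <- floor(px); y0 <- floor(py); fx <- px - x0; fy <- py - y0
    frame[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
      frame[y0 + 1, x0 + 2] * fx * (1 - fy) +
      frame[y0 + 2, x0 + 1] * (1 - fx) * fy +
      frame[y0 + 2, x0 + 2] * fx * fy
  }, numeric(1))
  expect_equal(pr$intensity[10], mean(vals), tolerance = 1e-10)
})

test_that("a band exiting the frame errors with the offending location", {
  frame <- matrix(0, 30, 30)
  expect_error(extract_profile(frame, rbind(c(2, 2), c(28, 28)),
                               pixel_size = 1, band_width = 10),
               "outside")
})

test_that("quadratic refinement is exact on sampled parabolas", {
  s <- seq(0, 40, by = 0.5)
  f <- function(x) 10 - 0.3 * (x - 12.34)^2
  g <- function(x) 8 - 0.2 * (x - 27.89)^2
  prof <- data.frame(position_um = s, intensity = pmax(f(s), 0) + pmax(g(s), 0))
  w <- detect_walls(prof)
  expect_equal(w$left_um, 12.34, tolerance = 1e-9)
  expect_equal(w$right_um, 27.89, tolerance = 1e-9)
  expect_equal(w$left_intensity, 10, tolerance = 1e-9)
})

test_that("Gaussian-ridge walls match a dense-grid oracle within 0.1 um", {
  set.seed(77)
  for (k in 1:100) {
    c1 <- runif(1, 8, 18)
    sep <- runif(1, 25, 55)
    c2 <- c1 + sep
    sd1 <- runif(1, 2, 4); sd2 <- runif(1, 2, 4)
    a1 <- runif(1, 0.8, 1.2); a2 <- runif(1, 0.8, 1.2)
    f <- function(x) a1 * exp(-0.5 * ((x - c1) / sd1)^2) +
      a2 * exp(-0.5 * ((x - c2) / sd2)^2)
    s <- seq(0, c2 + 15, by = 0.5)
    w <- detect_walls(data.frame(position_um = s, intensity = f(s)))
    oracle <- dense_wall_oracle(f, 0, c2 + 15, split = (c1 + c2) / 2)
    expect_lt(abs(w$width_um - (oracle[2] - oracle[1])), 0.1)
  }
})

test_that("wall positions are invariant under affine intensity transforms", {
  s <- seq(0, 60, by = 0.5)
  f <- function(x) exp(-0.5 * ((x - 15) / 3)^2) + exp(-0.5 * ((x - 45) / 3)^2)
  base <- detect_walls(data.frame(position_um = s, intensity = f(s)))
  tran <- detect_walls(data.frame(position_um = s,
                                  intensity = 3.7 * f(s) + 11))
  expect_equal(tran$left_um, base$left_um, tolerance = 1e-9)
  expect_equal(tran$right_um, base$right_um, tolerance = 1e-9)
})

test_that("monotonic profiles raise a two-walls-not-found error", {
  prof <- data.frame(position_um = 0:20, intensity = seq(0, 2, length.out = 21))
  expect_error(detect_walls(prof), "two walls not found")
})

test_that("constant-width synthetic vessels measure 50 um on every frame", {
  sim <- synth_vessel_video(vessel_sim_spec(
    n_frames = 12, image_shape = c(160, 80), baseline_width = 50,
    noise_sd = 0, jitter_max = 0, texture_amplitude = 0, seed = 5))
  tr <- diameter_series(sim$stack, rbind(c(40, 15), c(40, 144)))
  expect_true(all(abs(tr$width_um - 50) < 0.1))
  expect_true(all(tr$left_um < tr$right_um))
})

test_that("an all-dark stack aborts the diameter pipeline", {
  st <- frame_stack(array(0, dim = c(60, 40, 4)), 10, 0.5)
  expect_error(diameter_series(st, rbind(c(20, 5), c(20, 54))), "failed")
})

test_that("running average spreads an impulse and preserves constants", {
  x <- rep(50, 21); x[11] <- 60
  sm <- smooth_running_average(x, 5)
  expect_equal(sm[9:13], rep(52, 5))
  expect_equal(sm[1:5], rep(50, 5))
  expect_equal(smooth_running_average(x, 1), x)          # identity
  expect_equal(smooth_running_average(rep(3, 9), 5), rep(3, 9))
  expect_error(smooth_running_average(x, 4), "odd")
  expect_error(smooth_running_average(x, 23), "length")
})

test_that("response metrics implement ((MAX - MIN)/MIN) * 100", {
  tr <- data.frame(time_s = 0:29, width_um = c(rep(50, 12), rep(60, 18)))
  rm_ <- response_metrics(tr, laser_on = 10, laser_off = 25, min_search = 10)
  expect_equal(rm_$min_width_um, 50)
  expect_equal(rm_$max_width_um, 60)
  expect_equal(rm_$pct_change, 20)
  expect_equal(rm_$net_change_um, tr$width_um - 50)
  const <- data.frame(time_s = 0:29, width_um = rep(40, 30))
  rc <- response_metrics(const, 5, 20)
  expect_equal(rc$pct_change, 0)
  expect_true(all(rc$net_change_um == 0))
})

test_that("constriction swaps the roles of the extrema", {
  tr <- data.frame(time_s = 0:29, width_um = c(rep(50, 12), rep(40, 18)))
  rm_ <- response_metrics(tr, 10, 25, direction = "constriction")
  expect_equal(rm_$pct_change, (40 - 50) / 50 * 100)
})

test_that("response metrics validate their windows", {
  tr <- data.frame(time_s = 0:29, width_um = rep(50, 30))
  expect_error(response_metrics(tr, 20, 10), "laser_on")
  expect_error(response_metrics(tr, 25, 40), "cover")
})
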