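test_that("cardiac phase follows the bracketing R peaks", {
  r <- c(0, 0.5, 1.2)
  expect_equal(assign_cardiac_phase(0, r), 0)           # on an R peak
  expect_equal(assign_cardiac_phase(0.25, r), 0.5)      # RR midpoint
  expect_equal(assign_cardiac_phase(0.85, r), 0.5)      # second interval
  expect_equal(floor(assign_cardiac_phase(0.775, r) * 10), 3)
  expect_true(is.na(assign_cardiac_phase(-0.1, r)))     # before first
  expect_true(is.na(assign_cardiac_phase(1.3, r)))      # after last
})

test_that("phase 0.55 with 10 bins lands in bin index 5 (0-based)", {
  r <- c(0, 1)
  ph <- assign_cardiac_phase(0.55, r)
  expect_equal(floor(ph * 10), 5)
})

test_that("phase assignment is invariant to a global time shift", {
  set.seed(8)
  r <- cumsum(runif(20, 0.1, 0.2))
  lt <- runif(200, min(r), max(r) - 1e-6)
  expect_equal(assign_cardiac_phase(lt + 1000, r + 1000),
               assign_cardiac_phase(lt, r), tolerance = 1e-9)
})

test_that("respiratory gating rejects exactly the commanded window", {
  # 0.5 s period cosine: peaks at 0, 0.5, 1.0, ...
  fs <- 1000
  tg <- seq(0, 5, by = 1 / fs)
  resp <- time_trace(cos(2 * pi * tg / 0.5), fs)
  lt <- seq(0.602, 4.4, by = 0.01)   # grid avoids the exact window boundary
  acc <- respiratory_gate(lt, resp, exclusion_fraction = 0.2)
  near_peak <- vapply(lt, function(t) min(abs(t - seq(0, 5, 0.5))), numeric(1))
  expect_equal(acc, near_peak > 0.05 + 1e-9, tolerance = 0)
})

test_that("exclusion fraction 0 accepts everything, 1 rejects between peaks", {
  fs <- 1000
  tg <- seq(0, 3, by = 1 / fs)
  resp <- time_trace(cos(2 * pi * tg / 0.5), fs)
  lt <- seq(0.6, 2.4, by = 0.05)
  expect_true(all(respiratory_gate(lt, resp, 0)))
  expect_true(all(!respiratory_gate(lt, resp, 1)))
})

test_that("a flat respiration trace warns and accepts all lines", {
  resp <- time_trace(rep(0, 1000), 1000)
  expect_warning(acc <- respiratory_gate(c(0.1, 0.5), resp, 0.3),
                 "no respiratory peaks")
  expect_true(all(acc))
})

test_that("reconstruction of a static noiseless scene is identical across bins", {
  ls <- synth_linescan(n_lines_per_frame = 16, n_frames = 30,
                       modulation_depth = 0, noise_sd = 0, seed = 2)
  ph <- assign_cardiac_phase(ls$lines$acquisition_time_s, ls$truth$r_peaks_s)
  pb <- reconstruct_phase_bins(ls$lines, ph, n_bins = 10)
  expect_equal(pb$n_bins, 10L)
  expect_length(pb$means, 10)
  for (b in 2:10)
    expect_equal(pb$means[[b]], pb$means[[1]], tolerance = 1e-12)
})

test_that("bin means track the commanded cardiac modulation", {
  ls <- synth_linescan(n_lines_per_frame = 32, n_frames = 60,
                       cardiac_period = 0.12, modulation_depth = 0.3,
                       noise_sd = 1, seed = 3)
  ph <- assign_cardiac_phase(ls$lines$acquisition_time_s, ls$truth$r_peaks_s)
  pb <- reconstruct_phase_bins(ls$lines, ph, n_bins = 10)
  bm <- vapply(pb$means, mean, numeric(1), na.rm = TRUE)
  s_mid <- ls$truth$modulation((seq_len(10) - 0.5) / 10)
  expect_gte(cor(bm, s_mid), 0.95)
})

test_that("bin partition conserves accepted assignable lines", {
  ls <- synth_linescan(n_lines_per_frame = 16, n_frames = 20, seed = 4)
  ph <- assign_cardiac_phase(ls$lines$acquisition_time_s, ls$truth$r_peaks_s)
  set.seed(1)
  acc <- runif(length(ph)) > 0.3
  pb <- reconstruct_phase_bins(ls$lines, ph, acc, n_bins = 10)
  expect_equal(sum(pb$counts), sum(acc & !is.na(ph)))
})

test_that("vectorized bin assignment matches a per-line brute-force loop", {
  set.seed(9)
  r <- cumsum(runif(60, 0.08, 0.2))
  lt <- runif(10000, 0, max(r) + 0.1)
  ph <- assign_cardiac_phase(lt, r)
  bins <- ifelse(is.na(ph), NA_integer_,
                 pmin(floor(ph * 10), 9L) + 1L)
  expect_equal(bins, bin_assign_oracle(lt, r, 10))
})

test_that("ROI traces report per-frame means at frame timestamps", {
  fr <- array(7, dim = c(20, 30, 5))
  fr[11, 21, 3] <- 7 + 600                 # one bright pixel in frame 3
  st <- frame_stack(fr, frame_rate = 10, pixel_size = 1)
  tr <- extract_roi_trace(st, c(0, 29, 0, 19))
  expect_equal(tr$time_s, (0:4) / 10)
  expect_equal(tr$intensity[1], 7)
  expect_equal(tr$intensity[3], 7 + 600 / 600)
  expect_error(extract_roi_trace(st, c(10, 5, 0, 19)), "ROI")
  expect_error(extract_roi_trace(st, c(0, 40, 0, 19)), "ROI")
})

test_that("noiseless pacing transients couple 1:1 at the stated latency", {
  edges <- seq(0.5, 10, by = 0.5)          # 2 Hz pulses
  p <- pulse_train(edges, edges + 0.07)
  f <- synth_fluor_trace(p, latency = 50, rise = 10, decay = 100,
                         amplitude = 1, noise_sd = 0, seed = 1)
  pc <- pacing_coupling(f$trace, p)
  expect_equal(pc$coupling_fraction, 1.0)
  expect_true(all(abs(pc$latency_ms - 50) <= 1))
})

test_that("a transient-free noisy trace couples to nothing", {
  edges <- seq(0.5, 5, by = 0.5)
  p <- pulse_train(edges, edges + 0.07)
  f <- synth_fluor_trace(p, latency = 50, amplitude = 0, noise_sd = 0.01,
                         seed = 2)
  pc <- pacing_coupling(f$trace, p)
  expect_equal(pc$coupling_fraction, 0)
  expect_error(pacing_coupling(time_trace(rep(1, 100), 100), p),
               "zero-range")
})

test_that("the fluorescence kernel matches its closed form", {
  p <- pulse_train(1, 1.07)
  f <- synth_fluor_trace(p, latency = 50, rise = 10, decay = 100,
                         amplitude = 2, noise_sd = 0, sampling_rate = 1000,
                         seed = 3)
  onset <- f$truth$onset_times_s[1]
  # value one decay constant after onset: A (1 - e^(-decay/rise)) e^(-1)
  idx <- round((onset + 0.100) * 1000) + 1
  expect_equal(f$trace$values[idx],
               2 * (1 - exp(-10)) * exp(-1), tolerance = 1e-9)
  # two pulses 500 ms apart: onsets 50 ms after each edge
  p2 <- pulse_train(c(1, 1.5), c(1.07, 1.57))
  f2 <- synth_fluor_trace(p2, latency = 50, seed = 4)
  expect_equal(f2$truth$onset_times_s, c(1.05, 1.55))
})

test_that("generators are deterministic under a fixed seed", {
  a <- synth_linescan(seed = 5, noise_sd = 1, n_frames = 10)
  b <- synth_linescan(seed = 5, noise_sd = 1, n_frames = 10)
  expect_identical(a$lines$pixels, b$lines$pixels)
  sv <- vessel_sim_spec(n_frames = 4, jitter_max = 3, noise_sd = 1, seed = 6)
  expect_identical(synth_vessel_video(sv)$stack$frames,
                   synth_vessel_video(sv)$stack$frames)
})
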