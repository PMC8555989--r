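test_that("triangular R wave with analytic crossings gives exact duration", {
  # piecewise-linear beat: crosses zero at 10 ms and 22 ms, peak at 16 ms
  fs <- 1000
  t <- (0:99) / fs
  v <- rep(-0.1, 100)
  up <- t >= 0.010 & t <= 0.016
  down <- t > 0.016 & t <= 0.022
  v[up] <- (t[up] - 0.010) / 0.006
  v[down] <- (0.022 - t[down]) / 0.006
  v[t > 0.022] <- -0.1
  beats <- beat_table(0.016, p_peak_time_s = NA_real_)
  out <- measure_intervals(time_trace(v, fs), beats)
  expect_equal(out$r_duration_ms, 12, tolerance = 1e-6)
})

test_that("PR interval is P peak to the first QRS zero crossing", {
  fs <- 1000
  t <- (0:299) / fs
  v <- rep(-0.05, 300)
  up <- t >= 0.140 & t <= 0.150
  down <- t > 0.150 & t <= 0.160
  v[up] <- (t[up] - 0.140) / 0.010
  v[down] <- (0.160 - t[down]) / 0.010
  beats <- beat_table(0.150, p_peak_time_s = 0.100)
  out <- measure_intervals(time_trace(v, fs), beats)
  expect_equal(out$pr_interval_ms, 40, tolerance = 1e-6)
})

test_that("beats with no crossing in the search span are flagged missing", {
  fs <- 1000
  v <- rep(0.5, 500) + 0.5 * exp(-0.5 * (((0:499) / fs - 0.25) / 0.004)^2)
  beats <- beat_table(0.25)
  out <- measure_intervals(time_trace(v, fs), beats)   # never crosses zero
  expect_true(is.na(out$r_duration_ms))
  expect_equal(attr(out, "flagged"), 1L)
})

test_that("full-pipeline interval recovery stays within 2 ms of ground truth", {
  sim <- synth_ecg(ecg_sim_spec(duration = 25, heart_rate = 4, noise_sd = 0.02,
                                seed = 7))
  res <- analyze_ecg(sim$ecg, sim$ttl, "ventricular")
  tr <- sim$truth$beats
  m <- vapply(res$beats$r_peak_time_s,
              function(t) which.min(abs(tr$r_peak_time_s - t)), integer(1))
  expect_lte(median(abs(res$beats$r_duration_ms - tr$r_duration_ms[m]),
                    na.rm = TRUE), 2)
  expect_lte(median(abs(res$beats$pr_interval_ms - tr$pr_interval_ms[m]),
                    na.rm = TRUE), 2)
})

test_that("aligned average of identical beats has zero SD and the beat shape", {
  fs <- 1000
  one <- sin(2 * pi * (0:99) / 100)           # arbitrary 100-sample beat
  v <- c(rep(0, 50), rep(c(one, rep(0, 100)), 5), rep(0, 50))
  tr <- time_trace(v, fs)
  aligns <- 0.050 + 0.025 + (0:4) * 0.200     # sample 75 of each repeat
  avg <- aligned_average(tr, aligns, window = c(20, 20))
  expect_equal(avg$n_beats, 5)
  expect_true(all(avg$sd < 1e-12))
  expect_equal(avg$mean, v[(75 - 20):(75 + 20) + 1], tolerance = 1e-12)
})

test_that("opposite-noise segments cancel in the aligned mean", {
  fs <- 1000
  clean <- sin(2 * pi * (0:40) / 41)
  noise <- rnorm(41)
  v <- c(rep(0, 100), clean + noise, rep(0, 100), clean - noise, rep(0, 100))
  tr <- time_trace(v, fs)
  avg <- aligned_average(tr, c(0.120, 0.261), window = c(20, 20))
  expect_equal(avg$mean, clean, tolerance = 1e-12)
})

test_that("fixed-lag pulses summarize with zero SD", {
  fs <- 1000
  v <- rnorm(3000)
  tr <- time_trace(v, fs)
  aligns <- c(0.5, 1.0, 1.5, 2.0)
  p <- pulse_train(aligns - 0.014, aligns + 0.056)
  avg <- aligned_average(tr, aligns, window = c(60, 60), pulses = p)
  expect_equal(avg$laser_onset_mean_s, -0.014, tolerance = 1e-12)
  expect_equal(avg$laser_onset_sd_s, 0, tolerance = 1e-12)
  expect_equal(avg$laser_offset_mean_s, 0.056, tolerance = 1e-12)
})

test_that("aligned_average errors when no segment fits", {
  tr <- time_trace(rnorm(100), 1000)
  expect_error(aligned_average(tr, 5, window = c(60, 60)), "usable")
})
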