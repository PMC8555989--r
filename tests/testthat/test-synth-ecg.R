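test_that("unpaced beat count equals floor(duration * heart_rate)", {
  for (d in c(5, 8, 10.5, 20)) {
    for (hr in c(2, 4, 5, 8)) {
      sim <- synth_ecg(ecg_sim_spec(duration = d, heart_rate = hr,
                                    noise_sd = 0, jitter_sd = 0, seed = 3))
      expect_equal(nrow(sim$truth$beats), floor(d * hr),
                   info = sprintf("d=%g hr=%g", d, hr))
      expect_true(all(sim$truth$beats$class == "unstimulated"))
    }
  }
})

test_that("stimulated beats sit at the commanded latency after the pulse edge", {
  spec <- ecg_sim_spec(duration = 20, heart_rate = 5, stim_onset_time = 8,
                       pulse_rate = 5, stim_latency = 20, jitter_sd = 0,
                       noise_sd = 0, mode = "ventricular", seed = 2)
  sim <- synth_ecg(spec)
  stim <- sim$truth$beats[sim$truth$beats$class == "stimulated", ]
  expect_gt(nrow(stim), 30)
  lat <- stim$r_peak_time_s -
    sim$truth$pulses$rising_edges[stim$pulse_index]
  expect_equal(lat, rep(0.020, nrow(stim)), tolerance = 1e-12)
})

test_that("pulse length is honored: falling = rising + 70 ms", {
  sim <- sim_small_ecg(seed = 4, pulse_length = 70)
  p <- sim$truth$pulses
  expect_gt(length(p$rising_edges), 0)
  expect_equal(p$falling_edges - p$rising_edges,
               rep(0.070, length(p$rising_edges)), tolerance = 1e-12)
})

test_that("noiseless beats re-measured with analytic rulers match the spec", {
  # ideal-ruler check: zero-crossing interpolation on the raw (unfiltered)
  # noiseless waveform must reproduce the ground-truth intervals
  sim <- synth_ecg(ecg_sim_spec(duration = 10, heart_rate = 4, noise_sd = 0,
                                jitter_sd = 0, seed = 5))
  beats <- beat_table(sim$truth$beats$r_peak_time_s,
                      sim$truth$beats$p_peak_time_s)
  measured <- measure_intervals(sim$ecg, beats)
  expect_true(all(abs(measured$r_duration_ms -
                        sim$truth$beats$r_duration_ms) < 0.1))
  expect_true(all(abs(measured$pr_interval_ms -
                        sim$truth$beats$pr_interval_ms) < 0.1))
})

test_that("identical spec and seed give bit-identical output", {
  a <- sim_small_ecg(seed = 11, noise_sd = 0.05)
  b <- sim_small_ecg(seed = 11, noise_sd = 0.05)
  expect_identical(a$ecg$values, b$ecg$values)
  expect_identical(a$truth$beats, b$truth$beats)
  c <- sim_small_ecg(seed = 12, noise_sd = 0.05)
  expect_false(identical(a$ecg$values, c$ecg$values))
})

test_that("invalid simulation specs are rejected", {
  expect_error(ecg_sim_spec(sampling_rate = -1), "positive")
  expect_error(ecg_sim_spec(heart_rate = 2, r_duration_unstim = 600),
               "beat period")
  expect_error(ecg_sim_spec(pulse_rate = 5, stim_latency = 300),
               "pulse period")
  expect_error(ecg_sim_spec(dropout_prob = 1.5), "dropout")
})

test_that("pacing dropout removes the commanded fraction of beats", {
  spec <- ecg_sim_spec(duration = 60, heart_rate = 5, stim_onset_time = 2,
                       pulse_rate = 5, dropout_prob = 0.3, seed = 6)
  sim <- synth_ecg(spec)
  n_stim <- sum(sim$truth$beats$class == "stimulated")
  n_pulse <- length(sim$truth$pulses$rising_edges)
  expect_lt(n_stim, n_pulse)
  # binomial 3-sigma band around (1 - dropout) * pulses
  expect_lt(abs(n_stim - 0.7 * n_pulse), 3 * sqrt(n_pulse * 0.3 * 0.7) + 1)
})
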