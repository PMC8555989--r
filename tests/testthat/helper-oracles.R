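# Independent reference implementations used to cross-check the package.
# These deliberately use brute force / dense evaluation, not the code paths
# they verify.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p_value = min(1, p))
}

# Exhaustive masked normalized cross-correlation search over a shift grid.
# Correlation is taken over the reference interior (margin = radius), the
# same comparison window for every candidate shift.
shift_search_oracle <- function(ref, fr, mask, radius) {
  ny <- nrow(ref); nx <- ncol(ref)
  xs <- (radius + 1L):(nx - radius)
  ys <- (radius + 1L):(ny - radius)
  mm <- mask[ys, xs]
  a <- ref[ys, xs][mm]
  am <- a - mean(a)
  best <- -Inf; bdx <- 0L; bdy <- 0L
  for (dy in -radius:radius) for (dx in -radius:radius) {
    b <- fr[ys + dy, xs + dx][mm]
    bm <- b - mean(b)
    den <- sqrt(sum(am^2) * sum(bm^2))
    if (den == 0) next
    cc <- sum(am * bm) / den
    if (cc > best) { best <- cc; bdx <- dx; bdy <- dy }
  }
  c(bdx, bdy)
}

# Dense-grid argmax positions of a two-ridge analytic profile.
dense_wall_oracle <- function(f, lo, hi, split, step = 0.001) {
  gl <- seq(lo, split, by = step)
  gr <- seq(split, hi, by = step)
  c(gl[which.max(f(gl))], gr[which.max(f(gr))])
}

# Per-line loop: cardiac phase and bin assignment, one line at a time.
bin_assign_oracle <- function(line_times, r_peaks, n_bins) {
  vapply(line_times, function(t) {
    j <- NA_integer_
    for (i in seq_len(length(r_peaks) - 1L)) {
      if (t >= r_peaks[i] && t < r_peaks[i + 1L]) {
        ph <- (t - r_peaks[i]) / (r_peaks[i + 1L] - r_peaks[i])
        j <- as.integer(min(floor(ph * n_bins), n_bins - 1L) + 1L)
        break
      }
    }
    j
  }, integer(1))
}

# Shared small ECG simulation reused across detection/interval tests.
sim_small_ecg <- function(seed = 1, duration = 20, mode = "ventricular",
                          stim_onset = 8, ...) {
  synth_ecg(ecg_sim_spec(duration = duration, heart_rate = 5,
                         stim_onset_time = stim_onset, pulse_rate = 5,
                         mode = mode, seed = seed, ...))
}
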