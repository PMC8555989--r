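---
title: "Methods: optically paced ECG, vessel videometry, and cardiac-gated imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optically paced ECG, vessel videometry, and cardiac-gated imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopace)
```

`optopace` implements the quantitative analysis used in intravital
cardiovascular optogenetics: deciding which heartbeats were driven by a
laser pulse and measuring how pacing reshapes the ECG; tracking vessel
diameter through an opto-stimulation protocol; and reconstructing
motion-frozen frames from line-scanned fluorescence microscopy of a beating
heart. Because such recordings are rarely shareable, every analysis stage
is paired with a seeded synthetic-data generator that produces inputs with
exact ground truth, and the test suite measures the pipeline against that
truth.

## ECG analysis of optically paced beats

### Model and procedure

The raw ECG is conditioned in four steps: resampling onto a uniform grid
(linear interpolation; gaps longer than two sample periods are flagged),
zero-phase lowpass filtering with a passband edge of 100 Hz, optional
inversion, and normalization to median 0 / maximum absolute amplitude 1.
The filter is a 4th-order Butterworth applied forward-backward
(`filtfilt`), so intervals are not phase-shifted; trace ends are padded by
point-symmetric (odd) reflection to suppress edge transients. The filter
family and order are this package's choice — only the passband is a given
of the procedure.

R-wave peaks are local maxima above a height threshold (default 0.4
normalized units) separated by at least 50 ms; P waves are the maximum in a
window before each R peak (default 100 ms, with a 10 ms guard so the QRS
upstroke is not caught, and a prominence floor of 0.1 so flat segments
return "missing"). Detection thresholds are exposed in the configuration;
they are sensible defaults, not physiologic constants. Automated detection
is meant to be followed by manual curation, realized as a CSV
export/edit/re-import of the peak list (`write_peaks()` / `read_peaks()`).

Beat classification relies on stimulus latency windows, inclusive at both
ends:

* *unstimulated* — R peak before the first laser pulse rising edge;
* *stimulated* (ventricular pacing) — R peak 10–38 ms after the nearest
  preceding pulse **rising** edge;
* *stimulated* (nodal pacing) — P peak 38–52 ms after the nearest
  preceding pulse **falling** edge;
* *excluded* — anything else after stimulation onset.

Each pulse can capture at most one beat; when two beats qualify, the first
wins and later ones are excluded. Latencies are compared with a 1 ns
tolerance so that a beat at exactly 10.000 ms is inside the window while
9.999 ms is outside.

Intervals are measured on the normalized trace by zero crossings located
with linear interpolation between bracketing samples: the R-wave duration
is the time between the crossings flanking the R peak, and the PR interval
runs from the P peak to the first zero crossing of the QRS complex
(defined here as the last negative-to-positive crossing before the R peak;
search span 60 ms, configurable). Beats without a crossing in the span
keep missing intervals and are flagged.

Group comparisons use the two-sided Mann–Whitney test: exact when
`n_x + n_y <= 20` with no ties, otherwise the normal approximation with
tie and continuity corrections (`stats::wilcox.test` supplies the
computation; the test suite checks it against a full enumeration of rank
assignments). Note a limit we quantified while testing: for 5 vs 5
samples the continuity-corrected approximation can differ from the exact
p by up to ~0.017 at mid-range U; in the tail (p below ~0.15) it stays
within 0.01.

### Synthetic ECG

The generator schedules autonomous beats at the commanded heart rate until
stimulation onset, then one beat per laser pulse at the commanded latency
(R peak after the rising edge in ventricular mode; P peak after the
falling edge in nodal mode), with optional capture dropout. The beat
template was designed so that ground-truth intervals are analytic rather
than estimated:

* the R wave is a raised-cosine lobe whose zero crossings sit exactly
  `r_duration / 2` either side of the peak;
* negative Q and S half-sine lobes carry the trace through zero at those
  crossings; their width fraction equals their amplitude (default 0.2), a
  choice that makes the slope continuous across the crossing, so
  measuring the sampled waveform by linear interpolation is unbiased;
* P and T waves are Gaussians (amplitudes 0.25 and 0.15, SDs 8 and 15 ms)
  placed far enough from the QRS that their tails displace the crossings
  by well under 0.01 ms at the defaults.

Gaussian jitter (default SD 1 ms) is applied independently to beat times,
stimulation latencies, and per-beat R durations and PR intervals, so each
beat class carries a genuine distribution. Noise is additive white
Gaussian (baseline wander is available as a first-order random walk,
default off) — the simplest model that exercises the filters. What the
generator does *not* emulate: real QRS morphology and its beat-to-beat
variability, electrode artifacts, mains interference, and drifting heart
rates. A passing recovery test therefore shows the measurement chain is
correct and unbiased at realistic noise levels, not that detection is
robust to every artifact of an in vivo recording.

The headline reproduction runs the full pipeline at the study's printed
sample sizes — 115 unstimulated beats followed by 273 paced beats — with
a clearly separated effect (R duration 12 vs 18 ms; PR 40 vs 48 ms,
jitter SD 1 ms, noise SD 0.02 at 1 kHz). Sizing: 5 Hz autonomous rhythm
with pulses from 23.1 s, trace lengths 77.7 s (ventricular) and 77.8 s
(nodal) chosen so exactly 115 + 273 beats fit; with complete group
separation at these n the Mann–Whitney p saturates near 1e-54, far below
the p < 0.0001 criterion.

```{r}
sim <- synth_ecg(ecg_sim_spec(duration = 20, heart_rate = 5,
                              stim_onset_time = 8, pulse_rate = 5,
                              mode = "ventricular", seed = 1))
res <- analyze_ecg(sim$ecg, sim$ttl, "ventricular")
table(res$beats$label)
compare_beat_classes(res$beats, "r_duration_ms")[c("u", "p_value")]
```

## Vessel diameter from brightfield video

Frames are first stabilized by integer-pixel translation registration:
each frame is shifted to maximize its normalized cross-correlation (on
mean-subtracted pixels) with the first frame. The correlation is evaluated
over the reference frame's interior — a margin of one search radius
(default 20 px) is dropped so every candidate shift compares the same
reference pixels and zero-filled borders cannot bias re-registration —
and further restricted to the complement of an exclusion rectangle, the
image area contaminated by stimulation-laser light leakage. Ties prefer
the smaller shift, so an already-stable stack reports zeros. Sub-pixel
registration is deliberately not attempted; the diameter readout is
insensitive to residual sub-pixel translation because both walls move
together.

The diameter readout interpolates the intensity profile along a
user-specified line (bilinear interpolation, sampled every half pixel)
and averages, at each position, across a perpendicular band of 28.05 µm
total width — the band sample count is `band_width / pixel_size` rounded
to the nearest odd integer (51 samples at 0.55 µm/px). Averaging
perpendicular to the line (rather than along it) is this package's
reading of the ambiguous original description; it preserves the profile's
spatial resolution along the measurement direction while suppressing
noise. The two *most prominent* local maxima (prominence, not raw height,
so lumen glare is not mistaken for a wall) are each refined by a
quadratic fit over 3 samples, giving sub-sample wall positions and
intensities; their separation is the vessel width. Wall positions are
invariant under affine intensity transforms of the profile.

Width series are smoothed by a centered running average (default 5
frames — the original toolchain's window is unrecorded, so the default is
exposed in the configuration) and summarized as: MIN = minimum smoothed
width in the first 10 s after laser onset, MAX = maximum during the
activation epoch, percent change = ((MAX − MIN)/MIN) × 100, and a
net-change series (width − MIN). For constriction experiments the roles
of the extrema swap (`direction = "constriction"`), since the formula as
printed describes a dilation. Group comparisons of percent change use
pairwise Welch t-tests with step-down Šidák (Holm–Šidák) adjustment,
`adj_(i) = max_(j<=i) [1 − (1 − p_(j))^(m−j+1)]`; the underlying test is
this package's choice, as the source names only the correction.

The synthetic vessel renders two Gaussian-ridge sidewalls (SD 3 µm)
whose separation follows a commanded time course, over a dense granular
background texture that translates rigidly with per-frame integer jitter;
the vessel band itself is marked as the registration exclusion region
(walls move with dilation, not with frame motion). Recovery tests command
a step dilation (50 to 60 µm, stepping 1.5 s after laser onset to mimic
response latency) and a 5 µm sinusoid; at noise SD 2 (2% of wall
intensity) the pipeline reproduces the step's 20% change within 0.5 and
tracks the sinusoid with RMSE below 0.3 µm. The generator does not
emulate wall thickening during constriction, focus drift, or non-rigid
tissue deformation.

## Retrospective cardiac gating and pacing-coupled fluorescence

Each acquired image line carries a timestamp and a row index. Its cardiac
phase is `(t − R_prev)/(R_next − R_prev)` for the bracketing R peaks
(phase 0 at the R peak); lines outside the span of detected R peaks are
unassignable. Lines are optionally rejected by a respiratory gate: a
window centered on each detected inspiration peak, of total width a
fraction (default 0.3) of the respiratory cycle — the original criterion
lives in cited prior work, so this window is an explicit stand-in.
Accepted lines land in bin `floor(phase × n_bins)` (half-open bins, 10 by
default — one per 10% of the cardiac cycle) at their row position, and
contributions to each (bin, row) are averaged; empty rows are marked
missing with count 0, never fabricated. No sub-bin interpolation or
volume fusion is attempted.

Pacing-coupled calcium transients are detected on a running-median
detrended ROI trace as upward crossings of 0.2 × range that stay up (by
median) for at least 20 ms; the reported onset is walked back to the last
at-baseline sample, so latencies are not biased by the indicator's rise
time. Each pulse is matched to the first onset within 200 ms of its
rising edge; the coupling fraction is matched/total, 1.0 for clean 1:1
pacing. The synthetic trace uses a double-exponential kernel
`A (1 − e^(−τ/rise)) e^(−τ/decay)` (defaults 10/100 ms) that sums across
overlapping transients.

## Numerical conventions and degenerate inputs

* Times in seconds from trace start; intervals reported in ms; pixel
  coordinates 0-based; profile positions in µm from the first endpoint.
* Zero crossings and TTL edges by linear interpolation between bracketing
  samples; peak times at the nearest sample.
* Latency windows inclusive with 1 ns tolerance; phase bins half-open.
* Flat ECG input, zero-range fluorescence, monotonic profiles, all-dark
  stacks, and whole-frame exclusion regions raise typed errors; a single
  failed frame in a diameter series is logged and carried as `NA`
  (fatal only above 50% failures).
* Every generator draws from one seeded RNG per call and restores the
  caller's RNG state; a fixed seed gives bit-identical output.

## Problem sizes used by the test suite

Simulations in the tests are sized to exercise every code path at
realistic rates while keeping the default suite quick: ECG runs of
20–78 s at 1 kHz (up to 388 beats), vessel stacks of 21–80 frames at up
to 220 × 120 px with shift searches to ±10 px, line-scan sets of 16–64
rows per frame over 30–60 frames, and 10,000-line oracle sweeps. The
complete suite, including the end-to-end reproductions, runs in about a
minute.
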