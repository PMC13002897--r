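---
title: "Methods: seizure-suppression analysis for multifunctional neural probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seizure-suppression analysis for multifunctional neural probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`probeseize`, in the spirit of a methods section: what is computed, under
which assumptions, and which knobs matter.

## The experimental setting

A silicon probe shank carries 18 recording electrodes, 16 addressable
optical emitters staggered on a 55-µm longitudinal pitch, and one
microfluidic outlet near the middle of the array (~0.9 mm from the tip).
A convulsant injected through the outlet induces epileptiform activity;
long (10-s) continuous-wave optical pulses delivered from individual
emitters perturb it; the LFP recorded on the electrodes measures the
perturbation at each site. Short pulse trains (10 pulses at 5 Hz, 30 ms
each) probe stimulus-locked spiking instead.

## Preprocessing chain

The conditioning order is fixed and enforced by `preprocess()`:

1. **Common average referencing.** At every sample the mean across the
   in-brain, functional electrodes is subtracted from each of those
   electrodes. Non-functional channels (configured via `set_bad_channels()`)
   never enter the mean and are excluded from all statistics; channels
   outside the reference set pass through and are flagged.
2. **Zero-phase Butterworth bandpass**, 300–6000 Hz for spikes, 5–300 Hz
   for LFP. The prototype order is 4 (8 bandpass poles). The filter is
   designed and applied as a cascade of second-order sections because the
   expanded transfer-function form of an 8-pole bandpass with a 5-Hz corner
   at 30 kHz is numerically unstable in double precision. Zero phase is
   obtained by a forward–backward pass, so spike and LFP timing is unbiased
   (an impulse's peak is displaced by at most one sample). Edge handling is
   odd-reflect padding of about three cycles of the low corner
   (`3 * rate / low_hz` samples), which keeps start-up transients out of the
   data even at the LFP corner.
3. **Stimulus-artifact blanking.** The first and last 5 ms of every optical
   pulse are *masked*, not interpolated or zeroed: blanked samples are
   excluded from the sample count `T` of every power estimate and from
   spike windows. This preserves the definition of activity power as a mean
   over retained samples. (Whether the original analyses excluded or
   interpolated blanked samples is not documented; exclusion is this
   package's documented choice.)

## Seizure-suppression statistics

Activity power is `P = sum(v^2) / T` over valid samples (µV²). The
suppression ratio `SR = (P_pre − P_dur) / P_pre × 100` uses, by default, a
pre window equal in length to the CW pulse and immediately adjacent to it,
clipped against earlier pulses; the window lengths are a package default
(the source analyses display but do not state theirs). A per-pulse
immediately-preceding pre window is the default rather than one shared
pre-seizure baseline; the `pre_s` argument and `segment_around_pulses()`
expose the alternative. `sr_matrix()` assembles one SR per
(electrode, emitter) for a pattern; `fpsr()` reports the percentage of
strictly positive cells among non-missing ones (SR = 0 counts as
non-positive; missing cells — e.g. fully masked electrodes — are excluded
from the denominator). Pre/during/post comparisons use one-tailed
Mann–Whitney U tests with the suppression direction (during < pre) fixed as
the alternative, exact for combined n ≤ 20 without ties and the
normal approximation with tie correction otherwise; `stats::wilcox.test`
implements the test and an exhaustive rank-enumeration oracle verifies it in
the test suite.

`detect_seizure_onset()` is a pragmatic detector (the original workflow
identifies onset by inspection): median-across-channels power in a 1-s
moving window, flagged when it exceeds `k = 5` times the baseline median
for at least 2 s; the reported time is the start of the first supra-threshold
window, which biases the estimate early by up to ~0.8 s at strong
seizure-to-baseline contrast.

## Pulse-locked spiking analysis

`detect_spikes()` is a deterministic threshold detector standing in for full
spike sorting (clustering is out of scope; a ground-truth-label mode,
`spike_trains_from_ground_truth()`, bypasses detection entirely for pipeline
tests). Noise is estimated per channel as the median absolute deviation
scaled by 1/0.6745 (Gaussian-consistent robust SD); events exceed
`threshold_mads = 5` of it, are collapsed within a 1-ms refractory onto the
largest absolute peak, and are discarded if their waveform window touches a
masked sample. Unit quality reports the median-over-events absolute peak
(robust to outlier events), the spike count, and the ISI violation ratio at
a 2-ms refractory period, gating at ≥ 30 µV, ≥ 200 spikes, ≤ 0.5.

`fraction_in_pulse()` pools spikes over all pulses of an emitter (pooled
counting matches per-pulse rasters aggregated over ~150 pulses; per-repeat
averaging is a documented alternative, not implemented). The 230-ms
acquisition window opens `pulse_offset_s = 0.1` s before pulse onset — the
alignment is unstated in the source analyses; 100 ms gives near-symmetric
coverage at 5-Hz pulse spacing and is configurable. Baseline rates average
the 10 s preceding each train, truncated to exclude any pulse intervals.

## The synthetic-recording generator

`simulate_recording()` produces ground-truthed recordings with the
statistical structure the analysis assumes:

* **Noise**: equal-power mixture of white and 1/f-weighted Gaussian noise
  (`noise_sd_uv`, default 10 µV — typical cortical extracellular noise),
  the 1/f shaping flattened below 1 Hz.
* **Epileptiform component**: a periodic spike-and-wave train (sharp
  biphasic transient + slower opposing wave, ~250 ms support, dominant
  energy inside 5–300 Hz) at `burst_rate_hz = 2` (rhythmic after-discharge
  range), amplitude 500 µV at the outlet, decaying with electrode distance
  from the outlet (space constant 600 µm) and optionally sign-inverted
  across the outlet. Event centers sit at `onset + (k + 1/2) / rate` with
  bounded jitter: per-event amplitude jitter (relative SD 0.1) and timing
  jitter (5% of the period) emulate the irregularity of real
  after-discharges while guaranteeing that no event straddles a window or
  pulse boundary. That boundary guarantee is what makes the suppression
  closed form exact: during a CW pulse the component is multiplied by the
  suppression factor `s`, so during-window power is `s²` times pre-window
  power for windows that are integer multiples of the period. The default
  `s = sqrt(0.7)` encodes a 30% power reduction — the magnitude of the
  in vivo effect this analysis was built around. Sustained
  after-discharges are the default (`afterdischarge_decay_s = Inf`).
* **Polarity.** Referencing nearly cancels a spatially uniform component,
  so seizure simulations default to inversion across the outlet in the
  acceptance experiments — the configuration observed in vivo, where the
  LFP flips sign between electrodes above and below the injection site.
* **Units**: Poisson spiking at `baseline + gain_per_uw × power ×
  exp(−d_emitter / 100 µm)` during pulses (defaults: 1 Hz baseline, 6 Hz/µW
  gain — about 30 Hz pulse-locked at the 4.9-µW full power), rendered as a
  fixed 1.6-ms biphasic template whose amplitude decays across electrodes
  with a 25-µm space constant (plausible extracellular falloff; the exact
  form is a modeling choice).
* **Artifacts**: rectangular offsets of `edge_width_ms = 2` ms and 300 µV
  just inside both pulse edges — within the 5-ms blanking the analysis
  applies, matching the remedy without asserting an artifact shape.
* **Injections**: 1-Hz drift (300 µV) on the four outlet-proximal
  electrodes during injection epochs, mimicking injection-related recording
  artifacts.

All randomness derives from one master seed split deterministically into
noise / spike / seizure substreams, so identical configuration gives
bit-identical recordings. The generator does **not** model optical beam
propagation or tissue scattering, biophysical neuron dynamics, electrode
drift, spike-waveform diversity (one template), or spatially structured
noise; passing tests therefore demonstrate correctness of the estimators
under the stated statistical assumptions, not robustness to every feature
of real recordings. The spatial extent of suppression around the active
emitter is unknown; the default suppresses uniformly across channels, with
an optional exponential spatial kernel
(`suppression_space_constant_um`) as a modeling alternative, not a claim.

## Numerical and design choices

* Time is seconds (double); sample `i` is at `(i − 1)/rate`; sample windows
  are half-open `[a, b)` at sample resolution, so a 5-ms blank at 30 kHz is
  exactly 150 samples.
* Channel ids are 1-based integers matching electrode labels; display
  numbering is a presentation concern.
* SR is undefined (missing, with a warning) when `P_pre = 0`; power is an
  error on zero valid samples; a fully masked channel yields an empty spike
  train with a warning.
* Regression for flow resistance is through the origin (zero pressure must
  give zero flow); impedance SD uses the n−1 convention.
* Pipeline reports embed a hash of the analysis configuration (excluding
  the output directory) and the package version rather than timestamps, so
  identical runs are byte-identical.
* The recording container is matrix-backed (time × channel); analysis
  results are tibbles designed for dplyr/ggplot2 workflows.

## Problem sizes in the test suite

The suite exercises the full-scale configuration once — a 5-minute,
18-channel, 30-kHz recording with six 10-s CW pulses, yielding the
17 × 6 = 102-cell SR matrix — and otherwise uses a compact 8-electrode /
4-emitter layout at 15 kHz with 4-s pulses, which preserves every
property under test (the sampling theorem constraint, window/period
alignment, burst-to-noise ratios) at a fraction of the cost. Closed-form SR
recovery runs 10 seeds per suppression factor; onset detection 10 seeds;
rate recovery uses 150 pulses as in the pulse-train protocol.

## Known limitations

* Threshold detection under-counts spikes near blanked pulse edges and
  within refractory collisions; recovery-style tests therefore use the
  ground-truth-label mode, and detection is validated on clean separations.
* With few channels, common average referencing folds a fraction of each
  spike into every other channel; spike analyses on very small layouts
  should treat non-home channels' detections as reference ghosts.
* The onset detector reports the start of the first supra-threshold window
  (early bias < 1 s); it is a recovery tool for synthetic data, not a
  clinical seizure detector.
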