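---
title: "Validating wearable heart-rate sensors against criterion ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable heart-rate sensors against criterion ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvagree)
library(dplyr)
```

## The measurement problem

Photoplethysmography (PPG) wearables estimate each heartbeat from the
systolic peak of an optical blood-volume signal. Compared with the sharp
R-peak of an ECG, the PPG waveform is blunt, so the device's internal peak
detector misses beats, invents beats, and jitters in time — increasingly so
with movement — and each device timestamps on its own clock. A validation
study therefore records a candidate device and a criterion ECG
simultaneously over a set of experimental conditions (seated rest, cognitive
tasks, posture changes, walking, biking, ...) and asks, per condition: how
usable is the device's signal, and how well do the features derived from it
agree with the criterion?

`hrvagree` implements that comparison as a deterministic pipeline over tidy
tables. The universal currency is the **IBI series**: one row per interbeat
interval with its epoch timestamp in integer milliseconds. An interval is
anchored at the beat that *closes* it. Exports rarely say whether their
timestamp marks the opening or closing beat; we fix the closing-beat
convention once and apply it everywhere (ingestion, segmentation,
synchronization, resampling), which is what matters for consistency — a
global one-beat shift is absorbed by the synchronization step anyway.

## Synchronization

Device clocks differ from the criterion clock by an unknown, approximately
constant offset. `estimate_lag()` renders both streams as piecewise-constant
instantaneous heart-period step functions sampled on a shared 4 Hz grid
(phase-aligned to the epoch so two independently sampled streams share grid
points) and returns the integer-grid lag within ±`max_lag_s` that maximizes
the Pearson correlation of the overlapping samples, requiring at least 60 s
of overlap. Ties break toward the smallest absolute lag, a best correlation
below 0.3 raises a manual-review flag, and `lag_override` lets the analyst
pin a lag by hand. The 4 Hz grid mirrors the spectral resampling rate; it
quantizes the recovered lag to 250 ms, far finer than the 3-minute condition
windows the alignment has to serve. Drift (non-constant skew) is out of
scope: recordings are around 90 minutes, over which consumer clock drift is
small relative to that quantum.

Note that heavy beat-level corruption lowers the attainable correlation even
at the true lag, because missed beats change the IBI values themselves; the
flag marks the estimate as less trustworthy, not necessarily wrong.

## Segmentation

Condition windows are half-open `[start, end)` and membership is by interval
onset. Half-openness makes adjacent windows partition time without double
counting; a beat exactly on a boundary belongs to the later window. Windows
with no beats are retained as empty segments because downstream quality
classification distinguishes "device recorded nothing" from "no beats in
this window".

## Artifact correction

Cleaning happens per segment, in two passes of flag-then-interpolate:

1. **Range filter**: intervals strictly below 300 ms or strictly above
   2000 ms are physiologically implausible for adults and are flagged.
   Values exactly on a bound are kept.
2. **Karlsson neighbor-mean rule**: an interior interval is flagged when its
   absolute deviation from the mean of its two neighbours exceeds a
   coefficient *c* times that mean; the first and last intervals are never
   flagged. Neighbor means are computed on the values as they stand when the
   pass starts and all flags are applied simultaneously, so the result does
   not depend on scan order. One pass is run per cleaning call; this is the
   rule exactly as written, and repeated passes would blur the artifact
   count's meaning.

Flagged values are replaced — not deleted — by linear interpolation over
beat index between the nearest unflagged neighbours; runs interpolate across
the run, and flagged extremes take the nearest unflagged value. Index-based
interpolation is the natural choice when the timestamps adjacent to an
artifact are themselves untrustworthy. Both kinds of replacement count as
artifacts; the union is recorded in the `interpolated` mask.

The coefficient is **personalized**: some individuals have naturally high
beat-to-beat variability, and a fixed 0.25 would shred their data.
`tune_threshold()` starts at 0.25 and escalates in steps of 0.05 until the
Karlsson rule flags nothing on any segment of that participant's criterion
series (which expert scoring has already rendered artifact-free); the
resulting coefficient is shared by all of the participant's devices and
conditions. Escalation is capped at 1.0 — a criterion series still flagged
at a deviation ratio of 1 has something wrong with it that thresholding
should not mask, so the cap is a hard error advising manual review.

## Features

- **Mean HR** `= 60000 / mean(IBI)` in bpm.
- **RMSSD** `= sqrt(mean(diff(IBI)^2))` in ms (the `N−1` divisor over the
  `N−1` successive differences).
- **HF power**: the IBI series is resampled onto a uniform 4 Hz grid by a
  cubic spline, mean-removed, a Welch periodogram is computed (periodic Hann
  window, 256-sample segments — 64 s, giving ~0.016 Hz resolution — at 50%
  overlap, density scaling), and the density is integrated over
  0.12–0.40 Hz (7.2–24 breaths per minute) by the trapezoidal rule. Units
  ms². Segments spanning under 60 s return `NA` rather than an unstable
  estimate.

Two numerical choices deserve justification. First, the **resampling
method**: piecewise-linear interpolation from beat-rate samples acts as a
low-pass filter with amplitude response roughly `sinc²(fT)` (T the mean
heart period), which at 0.25 Hz and 900 ms beats removes ~29% of a tone's
power — a large systematic HF bias. A cubic spline tracks respiratory-band
oscillations with under 2% power error at typical heart rates, so the
spline is used. Second, **detrending**: only the mean is removed (plus the
per-segment demeaning inherent to Welch). Polynomial detrending would add a
degree of freedom the comparison does not need, since identical settings are
applied to device and criterion and the statistics compare the two within
participant.

The Welch settings are recorded in the result's parameter list so a report
is auditable; HF values from other tools will differ somewhat under other
settings, which is why agreement — not absolute parity with any particular
library — is the quantity of interest.

## Signal quality

Per segment: *missing* if the device produced no recording at all
(connectivity failure, unreadable export); otherwise *poor* if the detected
beat count deviates by more than 30% from the criterion count **or**
artifacts exceed 30% of detected beats; otherwise *acceptable*. Both
comparisons are strict inequalities, the count rule is symmetric in
direction (over-detection counts too), and a recorded segment with zero
beats inside a window is a 100% count deficit — poor, not missing. The IBI
detection rate (device count as percent of criterion count) is averaged over
non-missing segments in the summary table.

Poor segments are **included** in the agreement statistics by default: in
field use there is no criterion to identify them, so excluding them would
flatter the device. `exclude_poor = TRUE` enables the sensitivity analysis.

## Movement

Wrist accelerometer counts are converted to g by the calibration ratio
(physical range / digital range, counts assumed zero-centred), high-passed
at 0.1 Hz (first-order Butterworth) to remove gravity, reduced to the
per-sample Euclidean norm, and averaged per condition. The filter is applied
forward–backward: the order is fixed at one by convention, and zero-phase
application avoids shifting movement energy across condition boundaries. The
input is padded by odd reflection before filtering because the
forward–backward pass otherwise leaves a startup transient of several
seconds at the trace edges, inflating the mean magnitude of quiet
conditions.

## Agreement statistics

Observations are participant-level feature values within one device ×
condition cell, pairwise complete, with the per-cell n always reported.

- **MAAPE** `= 100 × mean(arctan(|device − criterion| / |criterion|))`.
  The arctangent bounds each pair's error at π/2, so gross overestimation of
  a near-zero reference (common for RMSSD in movement conditions) cannot
  blow up the mean; the scale runs from 0 to 100·π/2 ≈ 157.08. Its
  confidence interval is t-based over the per-pair transformed errors.
- **Regression**: OLS of device on criterion; slope, intercept, Pearson *r*,
  two-sided p for zero slope, slope SE. *r* is banded on |r| as negligible
  (< 0.30), low, moderate, high, very high (≥ 0.90), boundaries assigned
  upward. p-values are Bonferroni-adjusted within feature; the family size
  defaults to the number of device × condition cells present for that
  feature and is configurable (`bonferroni_m`) and recorded.
- **Bland–Altman**: differences are device − criterion; bias is their mean,
  limits of agreement bias ± 1.96 × sample SD, bias CI via
  `t(n−1)·sd/√n`, LoA CIs via the large-sample variance `3·sd²/n` with a
  normal quantile. RMSSD and HF are log-transformed (LnRMSSD, LnHF) for
  regression and Bland–Altman, as their sampling distributions are strongly
  right-skewed; MAAPE stays on the raw scale.

## The simulator and what passing tests mean

`simulate_criterion()` generates beats iteratively: the next interval is
`mean_ibi + rsa_amp·sin(2π·rsa_freq·t) + N(0, noise_sd)`, rounded to integer
ms. The sinusoid models respiratory sinus arrhythmia at a default 0.25 Hz
(15 breaths/min, mid-band), giving HF a closed-form target of `rsa_amp²/2`;
the defaults (800 ms mean period, 40 ms RSA, 20 ms noise) describe a seated
adult. `corrupt_series()` derives a device stream by operating on
reconstructed peak times — where miss/extra events physically happen — with,
in order: constant clock offset, per-beat deletion (intervals merge),
per-interval insertion at a uniform point (intervals split), Gaussian peak
jitter, and dropout windows. `simulate_accel()` plants per-condition RMS
movement levels (default contrast: ~0.01 g seated vs ~0.16 g walking) under
a 1 g gravity vector. Everything is deterministic under the seed; derived
per-participant seeds are decorrelated with an RNG burn-in.

The simulator emulates the *artifact structure* of PPG data — missed and
spurious beats, jitter, dropouts, clock offset — with known ground truth, so
end-to-end tests can assert exact recovery (a perfect device must give
MAAPE 0, r = 1, bias 0 after a planted 5 s offset is recovered; planted
missingness must reappear in the quality table). It does **not** emulate
waveform-level physics: motion-correlated artifact bursts, skin-tone or
perfusion effects, sensor-specific peak-detector quirks, or respiratory
rates wandering out of band. Passing tests therefore demonstrate that the
pipeline measures what it claims on data with known truth — not that any
particular physical device is accurate.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 3–24 simulated
participants with 2–3 conditions of 2 minutes each — enough beats
(~150 per segment) for stable features while keeping a full run in seconds.
Spectral oracles use 5-minute tones (the shortest span where leakage is
comfortably inside a 10% tolerance). Stochastic recovery checks use binomial
or 3-Monte-Carlo-SE tolerances at their stated n. The pipeline itself
contains no randomness: rerunning `run_pipeline()` on the same inputs
reproduces the JSON report byte for byte.

## Known limitations

- A single constant lag per recording; clock drift is not modelled.
- Single-pass Karlsson cleaning cannot fix long runs of adjacent artifacts;
  such segments are meant to be caught by the 30% quality rules instead.
- HF depends on resampling and Welch settings; values are comparable within
  a report, not across tools with different settings.
- The Avro container some vendors use for peak exports is not parsed; peaks
  are exchanged as a plain one-column CSV (`peak_time_ms`).
- LoA confidence intervals use the large-sample approximation, which is
  optimistic below n ≈ 10 per cell.
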