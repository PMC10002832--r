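---
title: "Oscillometric blood pressure from a pinhole finger clip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillometric blood pressure from a pinhole finger clip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscilloclip)
```

# The measurement principle

Oscillometry infers arterial pressure from how the amplitude of the
pulse-volume oscillation changes as an externally applied pressure sweeps
past the arterial pressure range: the oscillation is largest when the
external pressure equals mean arterial pressure (MAP, zero transmural
pressure) and shrinks on either side. A cuff sweeps that pressure
continuously; the device modelled here subsamples it instead with 20
discrete finger-force levels on a spring-loaded clip pressed against a
smartphone camera.

The clip encodes two signals in every camera frame:

* **Force** in the *size* of the pinhole projection: pressing compresses a
  spring (`F = preload + k x`, k = 0.49 N/mm, preload = 0.1 N, travel
  6.7 mm), moving the pinhole toward the camera so the projected circle
  grows. Over the 10 mm contact disk the achievable contact pressure runs
  from 9.55 mmHg (0.1 N) to 323 mmHg at the full 3.383 N; with the
  conventionally rounded 3.3 N ceiling that is the commonly quoted
  9.5--315 mmHg range. Both numbers are surfaced by `DeviceSpec()`'s show
  method.
* **Pulse** in the *brightness* of the projection: with more blood in the
  fingertip more light is absorbed, so the projection darkens on each
  heartbeat (PPG).

`projectionDiameter()` maps compression to projected size **linearly**
between the two calibration endpoints. A true similar-triangles pinhole
model is nonlinear in compression, but the app-side inverse
(`forceScaleFromDiameter()`) works "in proportion" between the recorded 0%
and 100% circle sizes, so the simulator generates exactly the model the
inverse assumes; the choice is isolated in one function so a geometric
model can be swapped in. Proportionality is in *diameter*, not area,
because the decoded quantity is the diameter reconstructed from the pixel
area. Out-of-range diameters are clamped to [0, 100]% and flagged rather
than rejected, since real frames jitter past the calibration endpoints.

# Frame decoding

Frames are 8-bit grayscale. Per frame (`processFrame()`):

1. **Histogram equalization** (`equalizeFrame()`), the standard CDF remap
   `v' = round(255 (cdf(v) - cdf_min)/(N - cdf_min))`, normalizes baseline
   brightness differences (blood volume, skin) before thresholding. A
   constant frame is returned unchanged — the formula is 0/0 there — and
   rank order is always preserved.
2. **Area and diameter** (`measureProjection()`): the area is the count of
   pixels *strictly* above intensity 20 in the equalized frame; the
   diameter is `2 sqrt(area/pi)`. "Above 20" is read as strict and
   centralized in one constant; no connected-component step is used, so
   the simulator keeps its background at a constant level below the
   threshold (a documented assumption — global thresholding would break
   if a noisy background occupied most of the histogram mass).
3. **PPG** (`extractPPG()`): the mean *raw* intensity over in-projection
   pixels whose raw value lies in [20, 254] inclusive — saturated (255)
   and dark (< 20) pixels are excluded. Region membership is decided on
   the equalized frame (same rule as the area); the mean is taken on the
   raw frame because equalization would distort the brightness signal that
   carries the pulse. Whether the app applies its thresholds pre- or
   post-equalization is not pinned down; this split (region
   post-equalization, values raw) is the package's documented choice.

The force trace shown to a user is smoothed by a zero-phase Butterworth
low-pass (`smoothForceTrace()`, 0.4 Hz cutoff, order 2 applied
forward-backward) purely for display: it passes drift with unit DC gain and
attenuates the cardiac ripple (>= 0.8 Hz) by more than 20 dB. The cutoff and
order are package choices; the analysis path never uses this filter.

# The guided protocol as a state machine

`runSession()` re-implements the app's guidance headlessly. Twenty target
force scales are spaced evenly from 5% to 95% (`levelTargets()`). At each
level the indicator is RED until the measured scale enters the closed
tolerance band (target ± 2%), YELLOW while holding, GREEN after 2 s
continuously in-band, and the level completes after 5 more seconds of
recording; any out-of-band sample while YELLOW or GREEN discards the buffer
and restarts the level from RED. "User movement" is operationalized as the
same ± 2% excursion rule — no separate movement detector exists. The
retained samples are the **last 5 s** of the compliant hold, timing is
event-driven on sample timestamps (not wall clock), and levels are
attempted strictly in ascending order. The 2 s hold is counted inside the
7 s per-level budget, so a perfectly compliant session takes 140 s plus a
few sample periods of inter-level latency; `totalDuration()` reports the
span from the first stream sample to the last accepted one. A stream that
ends early raises a typed condition (`oscilloclip_partial_session`)
carrying the completed levels.

`stepIndicator()` exposes the per-sample transition function; the
vectorized scan inside `runSession()` is tested against a replay driven by
`stepIndicator()` on randomized streams.

# From PPG segments to the oscillogram

Each level's 5 s segment is band-passed at 0.5--10 Hz
(`bandpass()`, Butterworth order 2 forward-backward, zero phase). The
segment mean is removed first: the filter rejects DC in steady state, but a
~150-count baseline step at the segment edges would otherwise excite
boundary transients far larger than a weak pulse. Mirrored edge padding is
deliberately *not* used here — reflecting a mid-phase pulse seeds small
oscillatory artifacts that the pulse detector would count — whereas the
display low-pass does use mirrored padding, where it is what makes the
unit-gain contract hold on constants and ramps. The two stages differ
because their failure modes differ, and both choices are regression-tested.

`pulseAmplitude()` reduces a filtered segment to one number:

* candidate pulses are local maxima with topographic prominence of at
  least 5% of the segment's peak-to-peak range, separated by at least
  0.33 s (a 180 bpm ceiling; ties resolved in favour of the more
  prominent peak);
* each pulse's **amplitude** is its height above the higher of its two
  flanking troughs — the minima between it and the neighbouring retained
  pulses. For a near-periodic pulse train this equals the topographic
  prominence, but it stays local when pulses are near-equal in height
  (where the prominence reference walk would run to the window edge);
* only **complete** pulses are averaged: both flanking troughs must be
  interior local minima at least 0.5 s inside the window. The margin is
  about one settle constant of the 0.5 Hz band edge; troughs inside the
  unsettled zone bias the amplitude by several percent, enough to reorder
  adjacent oscillogram points. At 48--84 bpm this leaves 3--7 complete
  pulses per 5 s window;
* a segment with no complete pulse yields (0, 0) with a flag, never an
  error — absent perfusion must surface as data, not as a crash.

One mean amplitude per level against the contact pressure at the level's
target scale (`pressureAtScale()`) forms the 20-point subsampled
oscillogram (`buildOscillogram()`). `selectAndNormalize()` then drops the
lowest and highest levels (at the lowest force the finger can leave the
clip; at the highest the spring bottoms out) and min-max normalizes the
remaining 18 amplitudes to [0, 1] using only those 18 values.
Normalization is per-recording: endpoint calibration already makes scales
subject-relative, so a cohort-level normalization would reintroduce
between-subject brightness differences. An all-equal 18-vector raises a
typed degenerate-normalization error rather than silently emitting zeros.

Two QC rules (`qcExclusions()`) mirror the study's exclusions: a reference
pulse pressure strictly above 80 mmHg, and insufficient perfusion. The
in-study perfusion criterion (pulse-oximeter perfusion index <= 1%) is not
computable from camera data, so the package substitutes a noise-referenced
bar: the oscillogram maximum must exceed three times the median amplitude
of a pulse-free reference recording (`perfusionThreshold()`), which the
simulator provides.

# Blood pressure estimation

SBP and MBP are estimated by LASSO regression on the 18 normalized
oscillogram points (`fitSbpMbp()`, via glmnet). Features are used as-is —
they are already in [0, 1] — with an unpenalized intercept. The penalty is
chosen independently per target by seeded inner cross-validation (5-fold by
default) over a logarithmic grid from 10 down to 1e-4; the data source
names neither the penalty nor its selection, so these are package defaults.
The inner CV shrinks to `min(n, innerFolds)` folds on small training sets
(3-fold floor); below 3 rows the least-penalized value is used.

DBP is estimated by ordinary linear regression on the *predicted* SBP and
MBP (`fitDbp()`). Algebraically DBP = (3 MBP − SBP)/2 follows from the
one-third rule MBP = 1/3 SBP + 2/3 DBP (`mbpReference()`); the free
regression is nevertheless the default because it can absorb systematic
error in the upstream predictions. The algebraic path is used only when a
training set is too small (< 4) to fit the two-predictor model.

Evaluation uses leave-two-out cross-validation (`leaveTwoOutCV()`):
subjects are shuffled with a fixed seed and paired consecutively, giving 12
folds at n = 24; each subject is predicted exactly once by models that
never saw its fold. Inside each training set, the DBP model is fit on
*out-of-fold* SBP/MBP predictions from an inner leave-two-out pass at the
already-selected penalties — fitting it on in-sample predictions would leak
training-fit optimism into the DBP coefficients. `accuracyMetrics()`
reports MAE with the SD of absolute errors (the "±" convention adopted
here; the SD of signed differences is also reported), bias, and
Bland-Altman limits of agreement (bias ± 1.96 SD of differences).

# The simulator

The simulator replaces hardware and human with explicit models, so every
stage is testable without human data.

* **Envelope**: pulse amplitude
  `aMax · perfusion · exp(−(p − MAP)² / 2σ²)`, maximal exactly at MAP. The
  true envelope shape of the digital artery is not characterized anywhere,
  so the Gaussian is chosen for a known argmax that recovery tests can
  assert against; an asymmetric variant (wider flank below MAP) sits
  behind the same interface. The width is coupled to pulse pressure,
  σ = 0.75 (SBP − DBP), the classic oscillometric association — this
  coupling is what makes SBP identifiable from the envelope's shape, not
  just its location.
* **Waveform**: raised sinusoid at the subject's heart rate, darker with
  more blood. Only peak-to-trough amplitude is consumed downstream, so
  dicrotic-notch morphology is out of scope.
* **User**: first-order exponential approach to each target
  (τ = 0.5 s default), Gaussian tremor (0.5% force scale), and seeded
  excursions (0.5/min, 0.3 s deflections past the band) that force level
  restarts — a compliant-but-imperfect operator. With all three at zero
  the session completes in the minimum time.
* **Noise**: per-pixel Gaussian noise inside the rendered disk
  (frame path), an equivalent measurement-level PPG noise in the
  frameless stream path, and a constant dark background below the area
  threshold (see the frame-decoding assumption above).
* **Cohort**: reference pressures from a truncated bivariate normal
  matched to the validation cohort moments (SBP 116.8 ± 20.3, DBP
  73.5 ± 12.3 mmHg, correlation 0.7, resampled until SBP > DBP + 10);
  heart rate uniform on 48--84 bpm (3--7 pulses per window), pulse
  amplitude 30--60 intensity units, baseline 120--180. QC-failure
  subjects (zero perfusion; a fixed 160/75 subject with pulse pressure
  85) can be injected to exercise the exclusion rules.

Sampling is 30 Hz by default (a typical smartphone camera), configurable
everywhere through `ProtocolConfig()`/`FilterConfig()`.

What the simulator does **not** emulate: real PPG morphology and its
harmonics, motion blur, ambient-light leakage, autoexposure, skin-tone
optics, and any physiologic envelope asymmetry beyond the provided variant.
Passing recovery tests therefore demonstrates that the pipeline inverts its
own generative model faithfully — a necessary condition — not that it
reproduces human-study accuracy, which would require the original
recordings.

# Numerical choices and degenerate inputs

* Tolerance band closed (boundary samples in-band); pulse-pressure rule
  strict (exactly 80 keeps).
* Equalization of a constant frame is the identity; rounding is
  floor(x + 0.5) for platform determinism.
* Zero projection area is a valid flagged measurement (diameter 0), as is
  a pulse-free segment (amplitude 0, count 0).
* Session JSON is written with 17 significant digits so a round trip is
  bit-exact; unknown keys are preserved with a warning, missing required
  keys name themselves in the error.
* All randomness (cohort draws, tremor, excursions, fold assignment,
  inner-CV folds) flows from explicit integer seeds; helper `withSeed()`
  restores the caller's RNG state, so package calls never perturb user
  code.
* Problem sizes used by the test-suite recovery checks: cohorts of 24
  subjects at 30 Hz (about 4,200 samples per subject-session), three noise
  settings (PPG noise SD 0, 1.5, 5 intensity units), and 1,000 fuzzed
  protocol streams; chosen to exercise every code path at desk scale while
  the whole suite stays under a minute of simulation time. The MAE
  degradation check across the three noise settings allows a 0.5 mmHg
  sampling slack, about the seed-to-seed SD of the noiseless MAE.

# Known limitations

* The linear projection model and the linear force-scale inverse agree by
  construction; against a real pinhole geometry both would be biased in
  the same direction, which calibration absorbs only partially.
* The perfusion QC bar needs a pulse-free reference recording; on real
  data one would substitute a resting pre-measurement segment.
* With 18 features and 22 training subjects the LASSO operates deep in the
  regularized regime; reported accuracy on simulated cohorts reflects the
  generative model's smoothness and should not be read as a clinical
  claim.
* `renderFrame()` draws an ideal anti-alias-free disk; rasterization makes
  the decoded diameter accurate to ~0.2 px, well inside the 1 px
  round-trip contract, but real optics would add blur the decoder never
  sees.
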