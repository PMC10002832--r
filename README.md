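# oscilloclip

Cuffless oscillometric blood pressure estimation with a spring-loaded
pinhole clip pressed by a fingertip against a smartphone camera — the
full computational pipeline, plus a physics-grounded simulator that stands
in for the hardware and the human operator so every stage is testable
without clinical data.

**Who it is for:** researchers in mHealth sensing and physiological signal
processing who want a reproducible, headless implementation of
pinhole-clip oscillometry — to study the algorithmic pipeline, stress it
under controlled noise, or adapt it to related camera-based force/PPG
transducers.

## The measurement in one paragraph

A compression spring (k = 0.49 N/mm, 0.1 N preload, 6.7 mm travel) turns
finger force into displacement; a pinhole near the camera projects a
circle whose **size** encodes the applied force and whose **brightness**
carries the photoplethysmogram (more blood, more light absorbed, darker
projection). Over a 10 mm contact disk the applied pressure spans
9.5–315 mmHg (rounded; the exact chain gives 9.55–323 mmHg). A guided
protocol walks the user up 20 force levels from 5% to 95% of the
calibrated range, holding each within ±2% for 2 s before recording 5 s —
a 140 s minimum per session. Each 5 s PPG segment is band-passed at
0.5–10 Hz and reduced to its mean complete-pulse peak-to-trough
amplitude; amplitude versus applied pressure is the *subsampled
oscillogram*, whose envelope peaks at mean arterial pressure (MAP). After
dropping the two extreme levels, the 18 min–max-normalized points feed a
LASSO regression for systolic and mean BP; diastolic BP follows by linear
regression on those two predictions (MBP = ⅓ SBP + ⅔ DBP is the reference
rule). Accuracy is evaluated by leave-two-out cross-validation with
MAE/bias and Bland–Altman limits of agreement.

## Worked example

Simulate a 24-subject cohort, run every subject through the guided
protocol, build oscillograms, apply QC, and estimate BP with leave-two-out
cross-validation:

```r
library(oscilloclip)

DeviceSpec()
#> DeviceSpec: k = 0.49 N/mm, preload = 0.1 N, travel = 6.7 mm, contact = 10 mm
#>   projection: 40 -> 120 px; force 0.1 -> 3.383 N; pressure 9.6 -> 323.1 mmHg

run <- RunConfig(nSubjects = 24L, seed = 7L)
res <- runPipeline(run)

res$oscillograms[[3]]
#> Oscillogram: 20 levels, pressures 25.2 to 307.4 mmHg
#>   peak amplitude 45.75 at 99.5 mmHg (level 5 )

print(res$metrics, digits = 3)
#>   target  n  mae mae_sd  bias sd_diff loa_lo loa_hi
#> 1    SBP 24 2.97   2.72 0.509    4.04  -7.41   8.43
#> 2    MBP 24 1.73   1.72 0.273    2.45  -4.53   5.08
#> 3    DBP 24 2.21   1.91 0.234    2.95  -5.54   6.01
```

Subject 3's true pressures are 133.4/75.1 mmHg (MAP 94.5): the oscillogram
peaks at the 99.5 mmHg level, the discrete level nearest the true MAP —
the envelope localization that the whole method rests on. The metrics
table reads: across the 24 cross-validated subjects, mean absolute error
2.97 mmHg for SBP (SD of absolute errors 2.72), bias +0.51 mmHg, and 95%
Bland–Altman limits of agreement −7.4 to +8.4 mmHg — errors of inverting
the simulator's own generative model at its default tremor and noise, not
a clinical accuracy claim.

The pieces compose freely: `simulateMeasurementStream()` →
`runSession()` → `buildOscillogram()` → `selectAndNormalize()` →
`leaveTwoOutCV()` → `accuracyMetrics()`, with PNG-frame rendering
(`renderFrame()`, `readFrames()`) as an alternative front end to the
measurement stream. See the vignette
(`vignettes/oscillometric-pipeline.Rmd`) for the models, parameter
defaults and design decisions.

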