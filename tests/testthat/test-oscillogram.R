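test_that("band-pass gain matches the analytic frequency response", {
  fs <- 60
  cfg <- FilterConfig(fs = fs)
  bf <- signal::butter(cfg@order, c(0.5, 10) / (fs / 2), type = "pass")
  t <- seq(0, 30, by = 1 / fs)
  mid <- 600:1200
  for (f in c(0.05, 2, 20)) {
    y <- bandpass(sin(2 * pi * f * t), cfg)
    measured <- max(abs(y[mid]))
    expect_equal(measured, filtfiltGain(bf, f, fs),
                 tolerance = 0.1)
  }
  # constant input is rejected entirely
  expect_lt(max(abs(bandpass(rep(7, 300), cfg))), 1e-6)
  # cardiac band passes near unity at the protocol sampling rate
  cfg30 <- FilterConfig(fs = 30)
  y <- bandpass(sin(2 * pi * 2 * seq(0, 10, by = 1 / 30)), cfg30)
  amp <- max(abs(y[100:200]))
  expect_gt(amp, 0.9)
  expect_lt(amp, 1.1)
  # slow drift is attenuated hard
  yd <- bandpass(sin(2 * pi * 0.05 * seq(0, 60, by = 1 / 30)),
                 FilterConfig(fs = 30))
  expect_lt(max(abs(yd[500:1300])), 0.1)
  expect_error(bandpass(rep(0, 10), cfg), "too short")
})

test_that("peak prominence flags edge-truncated pulses as incomplete", {
  t <- seq(0, 5, by = 1 / 30)[-151]        # 5 s at 30 Hz
  x <- sin(2 * pi * 1.2 * t)
  pk <- peakProminences(x)
  # 6 maxima, but the first has no interior trough on its left
  expect_equal(nrow(pk), 6)
  expect_equal(sum(pk$complete), 5)
  expect_equal(pk$prominence[pk$complete], rep(2, 5), tolerance = 1e-2)
})

test_that("pulse amplitude averages complete-pulse prominences", {
  t <- seq(0, 5, by = 1 / 30)[-151]
  # with the 0.5 s edge guard the pulse at 4.375 s (right trough 4.79 s)
  # is also dropped, leaving 4 of the 5 complete pulses
  pa <- pulseAmplitude(sin(2 * pi * 1.2 * t), fs = 30)
  expect_equal(pa$meanAmplitude, 2, tolerance = 0.02)
  expect_equal(pa$count, 4L)
  # without the guard all five complete pulses count
  pa0 <- pulseAmplitude(sin(2 * pi * 1.2 * t), fs = 30, edgeGuardS = 0)
  expect_equal(pa0$count, 5L)
  expect_equal(pa0$meanAmplitude, 2, tolerance = 0.02)
  # flat signal: flagged degenerate, not an error
  flat <- pulseAmplitude(rep(0, 150), fs = 30)
  expect_equal(flat$meanAmplitude, 0)
  expect_equal(flat$count, 0L)
  expect_false(flat$valid)
  # complete pulses with different prominences average arithmetically:
  # the first peak is edge-truncated (prominence 1, incomplete), the
  # remaining two have prominences 4 and 2
  y <- c(0, 1, 0, -1, 0, 3, 0, -1, 0, 1, 0, -1, 0)
  pa2 <- pulseAmplitude(y, fs = 30, minSpacingS = 0, edgeGuardS = 0)
  expect_equal(pa2$meanAmplitude, 3)
  expect_equal(pa2$count, 2L)
})

test_that("pulse amplitude scales linearly with signal amplitude", {
  set.seed(5)
  t <- seq(0, 5, by = 1 / 30)
  x <- sin(2 * pi * 1.1 * t) + 0.2 * sin(2 * pi * 2.7 * t + 1)
  base <- pulseAmplitude(bandpass(x, FilterConfig(fs = 30)), 30)
  for (c in c(0.5, 3, 40)) {
    scaled <- pulseAmplitude(bandpass(c * x, FilterConfig(fs = 30)), 30)
    expect_equal(scaled$meanAmplitude, c * base$meanAmplitude,
                 tolerance = 1e-6)
    expect_equal(scaled$count, base$count)
  }
})

test_that("the oscillogram peaks at the level nearest mean arterial pressure", {
  subj <- SubjectTruth(124, 78)
  sess <- makeSession(subject = subj)
  osc <- buildOscillogram(sess)
  expect_length(amplitudes(osc), 20)
  expect_equal(pressures(osc), pressureAtScale(DeviceSpec(),
                                               levelScales(osc)))
  expect_equal(which.max(amplitudes(osc)),
               which.min(abs(pressures(osc) - subj@mapTrue)))
  # where the pulse is strong, counts sit in the expected 3-7 band
  strong <- amplitudes(osc) > 0.25 * max(amplitudes(osc))
  expect_true(all(pulseCounts(osc)[strong] %in% 3:7))
})

test_that("zero perfusion yields a flagged, noise-floor oscillogram", {
  subj <- SubjectTruth(120, 80, perfusion = 0)
  sess <- makeSession(subject = subj)
  osc <- buildOscillogram(sess)
  expect_true(all(amplitudes(osc) < 1e-6))
  expect_true(all(pulseCounts(osc) == 0))
})

test_that("an incomplete session cannot produce an oscillogram", {
  sess <- makeSession()
  broken <- sess
  broken@levels <- sess@levels[1:19]
  expect_error(buildOscillogram(broken), "levels")
})

test_that("feature reduction drops the endpoints then min-max normalizes", {
  mk <- function(a) Oscillogram(seq(5, 95, length.out = 20),
                                pressureAtScale(DeviceSpec(),
                                                seq(5, 95, length.out = 20)),
                                a, rep(5L, 20))
  fv <- selectAndNormalize(mk(c(99, seq(2, 36, by = 2), 99)))
  expect_length(fv, 18)
  expect_equal(min(fv), 0)
  expect_equal(max(fv), 1)
  # linear ramp stays linear after normalization
  expect_equal(fv, seq(0, 1, length.out = 18))
  # excluded endpoints never set the normalization range
  fv2 <- selectAndNormalize(mk(c(1000, 1:18, 1000)))
  expect_equal(max(fv2), 1)
  expect_equal(fv2[18], 1)
  # all-equal amplitudes: degenerate-normalization condition
  expect_error(selectAndNormalize(mk(rep(3, 20))),
               class = "oscilloclip_degenerate_normalization")
})

test_that("QC excludes wide pulse pressure and absent perfusion", {
  osc <- Oscillogram(seq(5, 95, length.out = 20),
                     pressureAtScale(DeviceSpec(),
                                     seq(5, 95, length.out = 20)),
                     c(1:10, 10:1), rep(5L, 20))
  expect_false(qcExclusions(osc, 160, 75)$keep)
  expect_equal(qcExclusions(osc, 160, 75)$reason, "pulse pressure > 80")
  # exactly 80 mmHg difference is retained (strict inequality)
  expect_true(qcExclusions(osc, 155, 75)$keep)
  # amplitudes below the perfusion bar are excluded
  qc <- qcExclusions(osc, 120, 80, perfusionThr = 50)
  expect_false(qc$keep)
  expect_equal(qc$reason, "insufficient perfusion")
  expect_equal(perfusionThreshold(c(1, 2, 3, 4, 100)), 9)
})
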