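test_that("the pulse envelope peaks at MAP and scales with perfusion", {
  s <- SubjectTruth(120, 75, aMax = 40, sigmaEnv = 30, perfusion = 0.8)
  expect_equal(envelopeAmplitude(s, s@mapTrue), 40 * 0.8)
  # symmetric one-sigma points
  expect_equal(envelopeAmplitude(s, s@mapTrue + 30),
               40 * 0.8 * exp(-0.5))
  expect_equal(envelopeAmplitude(s, s@mapTrue - 30),
               envelopeAmplitude(s, s@mapTrue + 30))
  # zero perfusion kills the envelope everywhere
  s0 <- SubjectTruth(120, 75, perfusion = 0)
  expect_equal(envelopeAmplitude(s0, seq(10, 300, by = 10)),
               rep(0, 30))
  # asymmetric form: argmax unchanged, flanks unequal
  sa <- SubjectTruth(120, 75, sigmaEnv = 30, envelope = "asymmetric")
  p <- seq(20, 300, by = 0.5)
  expect_equal(p[which.max(envelopeAmplitude(sa, p))], sa@mapTrue,
               tolerance = 0.5)
  expect_gt(envelopeAmplitude(sa, sa@mapTrue - 40),
            envelopeAmplitude(sa, sa@mapTrue + 40))
  expect_error(envelopeAmplitude(s, -5), "pExt")
})

test_that("subject truth enforces its physiological invariants", {
  expect_error(SubjectTruth(80, 90), "sbp")
  expect_error(SubjectTruth(120, 75, hr = 200), "hr")
  expect_error(SubjectTruth(120, 75, aMax = 200, baseline = 150),
               "intensity budget")
  s <- SubjectTruth(120, 75)
  expect_equal(s@mapTrue, 90)
  expect_equal(s@sigmaEnv, 0.75 * 45)
})

test_that("a compliant noise-free user completes in the minimum time", {
  st <- simulateMeasurementStream(SubjectTruth(120, 75),
                                  UserModel(0, 0, 0),
                                  noise = NoiseModel(ppgSd = 0), seed = 2)
  cfg <- ProtocolConfig()
  expect_equal(nrow(st), cfg@nLevels * (levelTotalS(cfg) * cfg@fs + 1))
  expect_lte(max(st$timestamp_s),
             cfg@nLevels * levelTotalS(cfg) + cfg@nLevels / cfg@fs + 1e-9)
  # deep occlusion: far above SBP the pulse disappears
  high <- st[st$force_scale > 90, ]
  expect_lt(diff(range(high$ppg)), 1e-3)
  # same seed reproduces the stream exactly; other seeds do not
  again <- simulateMeasurementStream(SubjectTruth(120, 75),
                                     UserModel(0, 0, 0),
                                     noise = NoiseModel(ppgSd = 0),
                                     seed = 2)
  expect_identical(st, again)
  other <- simulateMeasurementStream(SubjectTruth(120, 75),
                                     UserModel(0, 0.4, 1), seed = 3)
  expect_false(identical(st, other))
})

test_that("tremor and excursions lengthen but never break the session", {
  st <- simulateMeasurementStream(SubjectTruth(115, 70),
                                  UserModel(0.5, 0.6, 2), seed = 6)
  sess <- runSession(st, Calibration(40, 120))
  expect_length(sessionLevels(sess), 20)
  expect_gte(totalDuration(sess), 140)
})

test_that("rendered frames invert through the decoding stage", {
  dev <- DeviceSpec()
  cal <- Calibration(dev@projD0, dev@projD100)
  quiet <- NoiseModel(pixelSd = 0, ppgSd = 0)
  for (sc in seq(0, 100, length.out = 20)) {
    f <- renderFrame(sc, 137, dev, quiet)
    m <- processFrame(f, cal)
    dTrue <- dev@projD0 + (dev@projD100 - dev@projD0) * sc / 100
    expect_lt(abs(m$diameter_px - dTrue), 1)
    expect_lt(abs(m$ppg - 137), 1)
  }
  # uniform disk intensity is returned exactly
  expect_equal(extractPPG(renderFrame(50, 100, dev, quiet))$ppg, 100)
  # background-only content never registers area
  bg <- CameraFrame(matrix(5L, 64, 64))
  expect_equal(measureProjection(equalizeFrame(bg))$area, 0L)
  # a projection larger than the sensor is rejected
  expect_error(renderFrame(100, 100, dev, quiet, size = 100L),
               "does not fit")
})

test_that("simulated cohorts reproduce the target moments", {
  sims <- lapply(1:10, function(k) simulateCohort(40, seed = 100 + k))
  sbp <- unlist(lapply(sims, function(s) s$truths$sbp))
  dbp <- unlist(lapply(sims, function(s) s$truths$dbp))
  # truncation (SBP > DBP + 10) shifts the moments slightly; wide bands
  expect_lt(abs(mean(sbp) - 116.8), 3)
  expect_lt(abs(sd(sbp) - 20.3), 3)
  expect_lt(abs(mean(dbp) - 73.5), 3)
  expect_lt(abs(sd(dbp) - 12.3), 3)
  expect_true(all(sbp > dbp + 10))
  # determinism and seed sensitivity
  expect_identical(simulateCohort(6, seed = 1)$truths,
                   simulateCohort(6, seed = 1)$truths)
  expect_false(identical(simulateCohort(6, seed = 1)$truths,
                         simulateCohort(6, seed = 2)$truths))
})

test_that("QC-failure subjects are injected as specified", {
  sim <- simulateCohort(29, seed = 4, nZeroPerfusion = 4,
                        nHighPulsePressure = 1)
  expect_equal(sum(sim$truths$perfusion == 0), 4)
  expect_equal(sum(sim$truths$sbp - sim$truths$dbp > 80), 1)
  expect_equal(sim$truths$sbp[25], 160)
  expect_equal(sim$truths$dbp[25], 75)
})
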