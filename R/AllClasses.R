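## Central value classes. Per-sample measurements are deliberately NOT S4
## objects: a measurement stream is a plain data.frame (see measurementFrame())
## so that a 140 s session at 30 Hz stays cheap to manipulate.

#' Mechanical and optical specification of the finger clip
#'
#' Forward physics of the spring-loaded clip: a compression spring of
#' stiffness `springK` (N/mm) pre-loaded with `preloadN` newtons, allowed
#' `travelMm` millimetres of travel, pressing a circular platform of
#' `contactDiameterMm` millimetres onto the fingertip. The pinhole
#' projection on the camera sensor grows monotonically with compression,
#' from `projD0` pixels (no force) to `projD100` pixels (fully pressed);
#' these two endpoints are the simulator-side counterparts of the app's
#' 0%/100% force-scale calibration.
#'
#' @slot springK numeric(1), spring constant in N/mm.
#' @slot preloadN numeric(1), spring preload force in N.
#' @slot travelMm numeric(1), maximum compression travel in mm.
#' @slot contactDiameterMm numeric(1), diameter of the circular contact
#'   surface in mm.
#' @slot projD0 numeric(1), projection diameter in pixels at zero compression.
#' @slot projD100 numeric(1), projection diameter in pixels at full travel.
#' @export
setClass("DeviceSpec",
  representation(
    springK = "numeric", preloadN = "numeric", travelMm = "numeric",
    contactDiameterMm = "numeric", projD0 = "numeric", projD100 = "numeric"
  )
)

setValidity("DeviceSpec", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@springK) || object@springK <= 0)
    msg <- c(msg, "springK must be a single positive number")
  if (!one(object@preloadN) || object@preloadN < 0)
    msg <- c(msg, "preloadN must be a single non-negative number")
  if (!one(object@travelMm) || object@travelMm <= 0)
    msg <- c(msg, "travelMm must be a single positive number")
  if (!one(object@contactDiameterMm) || object@contactDiameterMm <= 0)
    msg <- c(msg, "contactDiameterMm must be a single positive number")
  if (!one(object@projD0) || !one(object@projD100) ||
      object@projD0 <= 0 || object@projD100 <= object@projD0)
    msg <- c(msg, "projection endpoints must satisfy projD100 > projD0 > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DeviceSpec
#'
#' Defaults describe the reference build: k = 0.49 N/mm, 0.1 N preload,
#' 6.7 mm travel, 10 mm contact diameter. Note that preload + k * travel =
#' 3.383 N; rounded to 3.3 N this yields the commonly quoted 9.5--315 mmHg
#' pressure range over the 10 mm contact disk (the unrounded ceiling is
#' 323 mmHg).
#'
#' @param springK spring constant, N/mm.
#' @param preloadN preload force, N.
#' @param travelMm maximum travel, mm.
#' @param contactDiameterMm contact disk diameter, mm.
#' @param projD0,projD100 projection diameter (px) at zero and full
#'   compression.
#' @return A [DeviceSpec-class] object.
#' @examples
#' spec <- DeviceSpec()
#' forceAtCompression(spec, 6.7)
#' @export
DeviceSpec <- function(springK = 0.49, preloadN = 0.1, travelMm = 6.7,
                       contactDiameterMm = 10, projD0 = 40, projD100 = 120) {
  new("DeviceSpec", springK = as.numeric(springK),
      preloadN = as.numeric(preloadN), travelMm = as.numeric(travelMm),
      contactDiameterMm = as.numeric(contactDiameterMm),
      projD0 = as.numeric(projD0), projD100 = as.numeric(projD100))
}

#' Force-scale calibration endpoints
#'
#' The projection diameter recorded with the finger resting on the clip
#' (`d0`, force scale 0%) and with the clip fully pressed (`d100`, force
#' scale 100%). All subsequent force readings are expressed in proportion
#' between these two endpoints.
#'
#' @slot d0 numeric(1), diameter in px at 0% force scale.
#' @slot d100 numeric(1), diameter in px at 100% force scale.
#' @export
setClass("Calibration", representation(d0 = "numeric", d100 = "numeric"))

setValidity("Calibration", function(object) {
  if (length(object@d0) != 1L || length(object@d100) != 1L ||
      !is.finite(object@d0) || !is.finite(object@d100) ||
      object@d0 <= 0 || object@d100 <= object@d0)
    "calibration must satisfy d100 > d0 > 0" else TRUE
})

#' @param d0,d100 diameters (px) at 0% and 100% force scale.
#' @return A [Calibration-class] object.
#' @rdname Calibration-class
#' @export
Calibration <- function(d0, d100)
  new("Calibration", d0 = as.numeric(d0), d100 = as.numeric(d100))

#' Guided-measurement protocol configuration
#'
#' The force ladder: `nLevels` target force scales equally spaced from
#' `scaleLo` to `scaleHi` percent. At each level the user must stay within
#' `tolerancePct` of the target; after `holdS` seconds continuously in-band
#' the indicator turns green and data are recorded for `recordS` seconds.
#' Any excursion discards the buffer and restarts the level. The nominal
#' per-level budget is `holdS + recordS` seconds (7 s by default, hence a
#' 140 s minimum for 20 levels).
#'
#' @slot nLevels integer(1), number of force levels.
#' @slot scaleLo,scaleHi numeric(1), first and last target force scale, %.
#' @slot tolerancePct numeric(1), half-width of the tolerance band, %.
#' @slot holdS,recordS numeric(1), hold and record durations, s.
#' @slot fs numeric(1), measurement sampling rate, Hz.
#' @export
setClass("ProtocolConfig",
  representation(
    nLevels = "integer", scaleLo = "numeric", scaleHi = "numeric",
    tolerancePct = "numeric", holdS = "numeric", recordS = "numeric",
    fs = "numeric"
  )
)

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
  if (!(object@scaleLo >= 0 && object@scaleLo < object@scaleHi &&
        object@scaleHi <= 100))
    msg <- c(msg, "need 0 <= scaleLo < scaleHi <= 100")
  if (object@tolerancePct <= 0) msg <- c(msg, "tolerancePct must be > 0")
  if (object@holdS < 0 || object@recordS <= 0)
    msg <- c(msg, "holdS must be >= 0 and recordS > 0")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nLevels,scaleLo,scaleHi,tolerancePct,holdS,recordS,fs see slots.
#' @return A [ProtocolConfig-class] object.
#' @rdname ProtocolConfig-class
#' @export
ProtocolConfig <- function(nLevels = 20L, scaleLo = 5, scaleHi = 95,
                           tolerancePct = 2, holdS = 2, recordS = 5,
                           fs = 30) {
  new("ProtocolConfig", nLevels = as.integer(nLevels),
      scaleLo = as.numeric(scaleLo), scaleHi = as.numeric(scaleHi),
      tolerancePct = as.numeric(tolerancePct), holdS = as.numeric(holdS),
      recordS = as.numeric(recordS), fs = as.numeric(fs))
}

#' Per-level time budget
#'
#' Hold plus record duration in seconds (7 s at the defaults).
#' @param config a [ProtocolConfig-class].
#' @return numeric(1), seconds.
#' @export
levelTotalS <- function(config) config@holdS + config@recordS

#' Band-pass filter configuration for per-level PPG segments
#'
#' @slot bandLo,bandHi numeric(1), passband edges in Hz (0.5--10 by default,
#'   bracketing the cardiac fundamental and its first harmonics).
#' @slot order integer(1), Butterworth section order; the filter is applied
#'   forward-backward, so the magnitude response is squared and the phase is
#'   zero.
#' @slot fs numeric(1), sampling rate, Hz.
#' @export
setClass("FilterConfig",
  representation(bandLo = "numeric", bandHi = "numeric", order = "integer",
                 fs = "numeric")
)

setValidity("FilterConfig", function(object) {
  if (!(object@bandLo > 0 && object@bandLo < object@bandHi &&
        object@bandHi < object@fs / 2))
    "need 0 < bandLo < bandHi < fs/2" else TRUE
})

#' @param bandLo,bandHi,order,fs see slots.
#' @return A [FilterConfig-class] object.
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(bandLo = 0.5, bandHi = 10, order = 2L, fs = 30) {
  new("FilterConfig", bandLo = bandLo, bandHi = bandHi,
      order = as.integer(order), fs = fs)
}

#' One completed force level
#'
#' The last `recordS` seconds of a compliant hold at one target force scale:
#' every retained sample is within the tolerance band, and `nRestarts`
#' counts the discarded attempts that preceded it.
#'
#' @slot levelIndex integer(1), 0-based level index.
#' @slot targetScale numeric(1), target force scale, %.
#' @slot pressureMmhg numeric(1), contact pressure at the target scale.
#' @slot nRestarts integer(1), number of discarded attempts.
#' @slot samples data.frame of measurements (see [measurementFrame()]).
#' @export
setClass("LevelRecording",
  representation(levelIndex = "integer", targetScale = "numeric",
                 pressureMmhg = "numeric", nRestarts = "integer",
                 samples = "data.frame")
)

#' A completed guided session
#'
#' @slot device the [DeviceSpec-class] in force.
#' @slot calibration the [Calibration-class] used to map diameters to force
#'   scale.
#' @slot config the [ProtocolConfig-class].
#' @slot levels list of [LevelRecording-class], ordered by ascending target.
#' @slot totalDuration numeric(1), seconds from the first stream sample to
#'   completion of the last level.
#' @export
setClass("SessionRecord",
  representation(device = "DeviceSpec", calibration = "Calibration",
                 config = "ProtocolConfig", levels = "list",
                 totalDuration = "numeric")
)

setValidity("SessionRecord", function(object) {
  msg <- character()
  if (length(object@levels) != object@config@nLevels)
    msg <- c(msg, sprintf("expected %d levels, got %d",
                          object@config@nLevels, length(object@levels)))
  tg <- vapply(object@levels, function(l) l@targetScale, numeric(1))
  if (length(tg) > 1L && any(diff(tg) <= 0))
    msg <- c(msg, "levels must be ordered by increasing target scale")
  if (object@totalDuration <
      object@config@nLevels * levelTotalS(object@config) - 1e-9)
    msg <- c(msg, "totalDuration below the protocol minimum")
  if (length(msg)) msg else TRUE
})

#' The subsampled blood-volume oscillogram
#'
#' One (applied pressure, mean pulse amplitude) point per force level: the
#' averaged peak-prominence amplitude of the band-passed PPG recorded during
#' the 5 s hold at that level, against the contact pressure implied by the
#' target force scale. Its envelope peaks near mean arterial pressure.
#'
#' @slot levelScales numeric, target force scales, %.
#' @slot pressures numeric, contact pressures, mmHg.
#' @slot amplitudes numeric, mean peak-prominence amplitudes (intensity
#'   units), one per level.
#' @slot pulseCounts integer, number of complete pulses found per level.
#' @export
setClass("Oscillogram",
  representation(levelScales = "numeric", pressures = "numeric",
                 amplitudes = "numeric", pulseCounts = "integer")
)

setValidity("Oscillogram", function(object) {
  n <- length(object@levelScales)
  if (length(object@pressures) != n || length(object@amplitudes) != n ||
      length(object@pulseCounts) != n)
    return("levelScales, pressures, amplitudes, pulseCounts must be aligned")
  if (any(object@amplitudes < 0)) return("amplitudes must be >= 0")
  TRUE
})

#' @param levelScales,pressures,amplitudes,pulseCounts see slots.
#' @return An [Oscillogram-class] object.
#' @rdname Oscillogram-class
#' @export
Oscillogram <- function(levelScales, pressures, amplitudes, pulseCounts) {
  new("Oscillogram", levelScales = as.numeric(levelScales),
      pressures = as.numeric(pressures), amplitudes = as.numeric(amplitudes),
      pulseCounts = as.integer(pulseCounts))
}

#' Estimator configuration
#'
#' @slot lambdaGrid numeric, decreasing grid of L1 penalties searched by the
#'   seeded inner cross-validation.
#' @slot innerFolds integer(1), folds of the inner CV used to pick lambda.
#' @slot seed integer(1), seed controlling fold assignment (outer pairing
#'   and inner lambda selection).
#' @export
setClass("EstimatorConfig",
  representation(lambdaGrid = "numeric", innerFolds = "integer",
                 seed = "integer")
)

setValidity("EstimatorConfig", function(object) {
  if (!length(object@lambdaGrid) || any(object@lambdaGrid <= 0))
    return("lambdaGrid must be nonempty and positive")
  if (object@innerFolds < 2L) return("innerFolds must be >= 2")
  TRUE
})

#' @param lambdaGrid,innerFolds,seed see slots.
#' @return An [EstimatorConfig-class] object.
#' @rdname EstimatorConfig-class
#' @export
EstimatorConfig <- function(lambdaGrid = exp(seq(log(10), log(1e-4),
                                                length.out = 60)),
                            innerFolds = 5L, seed = 1L) {
  new("EstimatorConfig", lambdaGrid = sort(lambdaGrid, decreasing = TRUE),
      innerFolds = as.integer(innerFolds), seed = as.integer(seed))
}

#' Ground truth for one simulated subject
#'
#' Generative parameters of the simulator: reference pressures, heart rate,
#' and the transmural-pressure-dependent pulse-amplitude envelope. The
#' envelope amplitude is maximal when the externally applied pressure equals
#' mean arterial pressure (`mapTrue`) and falls off with width `sigmaEnv`;
#' `perfusion` scales the whole envelope (0 = no detectable pulse).
#'
#' @slot sbp,dbp numeric(1), reference systolic/diastolic pressure, mmHg.
#' @slot mapTrue numeric(1), mean arterial pressure, 1/3 SBP + 2/3 DBP.
#' @slot hr numeric(1), heart rate, bpm (36--180 keeps 3--15 pulses per 5 s
#'   window; defaults sample 48--84 for the typical 3--7).
#' @slot aMax numeric(1), peak pulse amplitude, 8-bit intensity units.
#' @slot sigmaEnv numeric(1), envelope width, mmHg.
#' @slot baseline numeric(1), mean projection intensity (20--254).
#' @slot perfusion numeric(1) in [0, 1].
#' @slot envelope character(1), "gaussian" or "asymmetric".
#' @export
setClass("SubjectTruth",
  representation(sbp = "numeric", dbp = "numeric", mapTrue = "numeric",
                 hr = "numeric", aMax = "numeric", sigmaEnv = "numeric",
                 baseline = "numeric", perfusion = "numeric",
                 envelope = "character")
)

setValidity("SubjectTruth", function(object) {
  msg <- character()
  if (object@sbp <= object@dbp) msg <- c(msg, "sbp must exceed dbp")
  if (object@hr < 36 || object@hr > 180)
    msg <- c(msg, "hr must lie in [36, 180] bpm")
  if (object@perfusion < 0 || object@perfusion > 1)
    msg <- c(msg, "perfusion must lie in [0, 1]")
  if (object@baseline > 254 ||
      object@baseline - object@aMax * object@perfusion < 20)
    msg <- c(msg, paste("intensity budget violated: need baseline <= 254",
                        "and baseline - aMax*perfusion >= 20"))
  if (!object@envelope %in% c("gaussian", "asymmetric"))
    msg <- c(msg, "envelope must be 'gaussian' or 'asymmetric'")
  if (length(msg)) msg else TRUE
})

#' @param sbp,dbp,hr,aMax,sigmaEnv,baseline,perfusion,envelope see slots;
#'   `sigmaEnv = NULL` defaults to 0.75 * (sbp - dbp), coupling envelope
#'   width to pulse pressure as in cuff oscillometry.
#' @return A [SubjectTruth-class] object.
#' @rdname SubjectTruth-class
#' @export
SubjectTruth <- function(sbp, dbp, hr = 66, aMax = 45, sigmaEnv = NULL,
                         baseline = 150, perfusion = 1,
                         envelope = "gaussian") {
  if (is.null(sigmaEnv)) sigmaEnv <- 0.75 * (sbp - dbp)
  new("SubjectTruth", sbp = sbp, dbp = dbp,
      mapTrue = (sbp + 2 * dbp) / 3, hr = hr, aMax = aMax,
      sigmaEnv = sigmaEnv, baseline = baseline, perfusion = perfusion,
      envelope = envelope)
}

#' First-order model of the human operator
#'
#' The simulated user relaxes exponentially toward each new target with time
#' constant `approachTau`, jitters around it with Gaussian tremor of
#' standard deviation `tremorSd` (% force scale), and occasionally slips out
#' of the tolerance band (`excursionRate` events per minute, each a brief
#' out-of-band deflection that forces a level restart).
#'
#' @slot approachTau numeric(1), settling time constant, s (0 = instant).
#' @slot tremorSd numeric(1), tremor SD, % force scale.
#' @slot excursionRate numeric(1), excursions per minute.
#' @export
setClass("UserModel",
  representation(approachTau = "numeric", tremorSd = "numeric",
                 excursionRate = "numeric")
)

setValidity("UserModel", function(object) {
  if (object@approachTau < 0 || object@tremorSd < 0 ||
      object@excursionRate < 0)
    "approachTau, tremorSd and excursionRate must be >= 0" else TRUE
})

#' @param approachTau,tremorSd,excursionRate see slots.
#' @return A [UserModel-class] object.
#' @rdname UserModel-class
#' @export
UserModel <- function(approachTau = 0.5, tremorSd = 0.5,
                      excursionRate = 0.5) {
  new("UserModel", approachTau = approachTau, tremorSd = tremorSd,
      excursionRate = excursionRate)
}

#' Sensor noise model
#'
#' `pixelSd` is per-pixel Gaussian noise inside the rendered projection;
#' `ppgSd` is the equivalent measurement-level noise on the pooled PPG value
#' in the frameless stream path; `backgroundLevel` is the constant dark
#' floor outside the projection (kept below the 8-bit area threshold so the
#' background never contributes to the measured area).
#'
#' @slot pixelSd numeric(1), per-pixel noise SD, intensity units.
#' @slot ppgSd numeric(1), measurement-level PPG noise SD, intensity units.
#' @slot backgroundLevel numeric(1), background intensity (< 20).
#' @export
setClass("NoiseModel",
  representation(pixelSd = "numeric", ppgSd = "numeric",
                 backgroundLevel = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@pixelSd < 0 || object@ppgSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@backgroundLevel < 0 || object@backgroundLevel >= 20)
    msg <- c(msg, "backgroundLevel must lie in [0, 20)")
  if (length(msg)) msg else TRUE
})

#' @param pixelSd,ppgSd,backgroundLevel see slots.
#' @return A [NoiseModel-class] object.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(pixelSd = 2, ppgSd = 0.5, backgroundLevel = 5) {
  new("NoiseModel", pixelSd = pixelSd, ppgSd = ppgSd,
      backgroundLevel = backgroundLevel)
}

## ---- show methods -------------------------------------------------------

setMethod("show", "DeviceSpec", function(object) {
  cat("DeviceSpec: k =", object@springK, "N/mm, preload =", object@preloadN,
      "N, travel =", object@travelMm, "mm, contact =",
      object@contactDiameterMm, "mm\n")
  cat("  projection:", object@projD0, "->", object@projD100, "px;",
      "force", object@preloadN, "->",
      round(object@preloadN + object@springK * object@travelMm, 3), "N;",
      "pressure", round(pressureFromForce(object@preloadN,
                                          object@contactDiameterMm), 1),
      "->", round(pressureFromForce(
        object@preloadN + object@springK * object@travelMm,
        object@contactDiameterMm), 1), "mmHg\n")
})

setMethod("show", "Calibration", function(object) {
  cat("Calibration: d0 =", object@d0, "px (0%), d100 =", object@d100,
      "px (100%)\n")
})

setMethod("show", "ProtocolConfig", function(object) {
  cat("ProtocolConfig:", object@nLevels, "levels,", object@scaleLo, "to",
      object@scaleHi, "%, tolerance +/-", object@tolerancePct, "%\n")
  cat("  hold", object@holdS, "s + record", object@recordS, "s =",
      levelTotalS(object), "s/level; fs =", object@fs, "Hz; minimum session",
      object@nLevels * levelTotalS(object), "s\n")
})

setMethod("show", "SessionRecord", function(object) {
  nr <- sum(vapply(object@levels, function(l) l@nRestarts, integer(1)))
  cat("SessionRecord:", length(object@levels), "levels,",
      round(object@totalDuration, 1), "s total,", nr, "restarts\n")
})

setMethod("show", "Oscillogram", function(object) {
  cat("Oscillogram:", length(object@amplitudes), "levels, pressures",
      round(min(object@pressures), 1), "to", round(max(object@pressures), 1),
      "mmHg\n")
  i <- which.max(object@amplitudes)
  cat("  peak amplitude", round(object@amplitudes[i], 2), "at",
      round(object@pressures[i], 1), "mmHg (level", i - 1L, ")\n")
})

setMethod("show", "SubjectTruth", function(object) {
  cat("SubjectTruth: SBP/DBP =", object@sbp, "/", object@dbp,
      "mmHg (MAP", round(object@mapTrue, 1), "), HR", object@hr, "bpm,",
      "envelope", object@envelope, "sigma", round(object@sigmaEnv, 1),
      "mmHg, perfusion", object@perfusion, "\n")
})

## ---- accessors ----------------------------------------------------------

#' Oscillogram accessors
#'
#' @param x an [Oscillogram-class].
#' @return `amplitudes()`, `pressures()` and `levelScales()` return numeric
#'   vectors; `pulseCounts()` an integer vector.
#' @name oscillogram-accessors
NULL

#' @rdname oscillogram-accessors
#' @export
amplitudes <- function(x) x@amplitudes
#' @rdname oscillogram-accessors
#' @export
pressures <- function(x) x@pressures
#' @rdname oscillogram-accessors
#' @export
levelScales <- function(x) x@levelScales
#' @rdname oscillogram-accessors
#' @export
pulseCounts <- function(x) x@pulseCounts

#' Session accessors
#'
#' @param x a [SessionRecord-class].
#' @return `sessionLevels()` returns the list of [LevelRecording-class];
#'   `totalDuration()` the session duration in seconds; `nRestarts()` the
#'   per-level restart counts.
#' @name session-accessors
NULL

#' @rdname session-accessors
#' @export
sessionLevels <- function(x) x@levels
#' @rdname session-accessors
#' @export
totalDuration <- function(x) x@totalDuration
#' @rdname session-accessors
#' @export
nRestarts <- function(x)
  vapply(x@levels, function(l) l@nRestarts, integer(1))

#' Coerce an Oscillogram to a data.frame
#'
#' @param x an [Oscillogram-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data.frame with columns level, scale_pct, pressure_mmhg,
#'   amplitude, pulse_count.
#' @export
as.data.frame.Oscillogram <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(level = seq_along(x@amplitudes) - 1L,
             scale_pct = x@levelScales, pressure_mmhg = x@pressures,
             amplitude = x@amplitudes, pulse_count = x@pulseCounts)
}

#' Plot an oscillogram
#'
#' Pulse amplitude against applied contact pressure; the envelope peaks near
#' mean arterial pressure.
#'
#' @param x an [Oscillogram-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "Oscillogram", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@pressures, x@amplitudes, type = "b", pch = 19,
                   xlab = "applied pressure (mmHg)",
                   ylab = "mean pulse amplitude (intensity)", ...)
    invisible(x)
  })
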