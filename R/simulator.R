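## Physics-grounded stand-in for the hardware and the human operator.
## The clip's dual encoding is generated forward: the projection diameter
## tracks spring compression, and the projection brightness carries a
## raised-sinusoid pulse whose amplitude follows a transmural-pressure
## envelope peaking at mean arterial pressure.

#' Pulse-amplitude envelope at a given external pressure
#'
#' Oscillation amplitude of the blood-volume pulse as a function of the
#' externally applied contact pressure. Amplitude is maximal when the
#' external pressure equals mean arterial pressure (zero transmural
#' pressure) and decays with width `sigmaEnv`:
#' `aMax * perfusion * exp(-(p - MAP)^2 / (2 sigma^2))` for the Gaussian
#' form. The `"asymmetric"` form uses a wider flank below MAP
#' (`1.25 sigma`) than above (`0.75 sigma`), closer to empirical cuff
#' oscillograms, while keeping the argmax at MAP.
#'
#' @param subject a [SubjectTruth-class].
#' @param pExt external pressure, mmHg (vectorized, >= 0).
#' @return amplitude in intensity units.
#' @export
envelopeAmplitude <- function(subject, pExt) {
  stopifnot(is(subject, "SubjectTruth"))
  if (any(pExt < 0)) stop("pExt must be >= 0")
  dev <- pExt - subject@mapTrue
  sig <- rep(subject@sigmaEnv, length(pExt))
  if (subject@envelope == "asymmetric")
    sig <- ifelse(dev < 0, 1.25 * subject@sigmaEnv,
                  0.75 * subject@sigmaEnv)
  subject@aMax * subject@perfusion * exp(-dev^2 / (2 * sig^2))
}

#' Instantaneous PPG intensity
#'
#' More blood absorbs more light, so the projection darkens on each pulse:
#' `baseline - envelope * (1 + sin(2 pi f t)) / 2`. Only the peak-to-trough
#' amplitude is consumed downstream, so waveform morphology beyond the
#' raised sinusoid is not modelled.
#' @keywords internal
.ppgWave <- function(subject, pExt, t) {
  env <- envelopeAmplitude(subject, pExt)
  subject@baseline - env * (1 + sin(2 * pi * subject@hr / 60 * t)) / 2
}

#' Simulate a guided-session measurement stream
#'
#' Generates the (force scale, PPG) stream a compliant-but-imperfect user
#' would produce against the guidance state machine. For each target level
#' the simulated user approaches exponentially with time constant
#' `approachTau`, then holds with Gaussian tremor (`tremorSd`); seeded
#' excursions (`excursionRate` per minute, 0.3 s deflections past the
#' tolerance band) force the level to restart, exactly as the protocol
#' demands. The per-sample PPG is the pulse waveform at the pressure
#' implied by the momentary force scale, plus measurement noise
#' (`noise@ppgSd`). With `approachTau = 0`, `tremorSd = 0` and
#' `excursionRate = 0` the stream is perfectly compliant and the session
#' completes in exactly `nLevels * (holdS + recordS)` seconds.
#'
#' @param subject a [SubjectTruth-class].
#' @param user a [UserModel-class].
#' @param device a [DeviceSpec-class].
#' @param protocol a [ProtocolConfig-class].
#' @param noise a [NoiseModel-class].
#' @param seed integer seed; identical seeds yield identical streams.
#' @return measurement data.frame (see [measurementFrame()]) with
#'   `timestamp_s`, `diameter_px`, `area_px`, `ppg`, `force_scale`,
#'   `valid`.
#' @export
simulateMeasurementStream <- function(subject, user = UserModel(),
                                      device = DeviceSpec(),
                                      protocol = ProtocolConfig(),
                                      noise = NoiseModel(), seed = 1L) {
  stopifnot(is(subject, "SubjectTruth"), is(user, "UserModel"),
            is(noise, "NoiseModel"))
  withSeed(seed, {
    fs <- protocol@fs
    dt <- 1 / fs
    tol <- protocol@tolerancePct
    nRun <- as.integer(round(levelTotalS(protocol) * fs)) + 1L
    targets <- levelTargets(protocol)
    pExcursion <- 1 - exp(-user@excursionRate * levelTotalS(protocol) / 60)
    nExc <- max(1L, as.integer(round(0.3 * fs)))
    scaleNow <- 0
    chunks <- list()
    for (target in targets) {
      ## approach: first-order settling to just inside the band
      if (user@approachTau > 0 && abs(scaleNow - target) > tol / 2) {
        tEnd <- user@approachTau * log(abs(scaleNow - target) / (tol / 2))
        nApp <- ceiling(tEnd * fs)
        tApp <- seq_len(nApp) * dt
        chunks[[length(chunks) + 1L]] <-
          target + (scaleNow - target) * exp(-tApp / user@approachTau)
      }
      ## hold attempts until one full compliant run is produced
      tries <- 0L
      repeat {
        tries <- tries + 1L
        block <- target + rnorm(nRun, 0, user@tremorSd)
        if (tries <= 50L && runif(1) < pExcursion) {
          at <- sample.int(nRun - 1L, 1L)
          idx <- at:min(nRun, at + nExc - 1L)
          block[idx] <- target + sample(c(-1, 1), 1L) * (tol + 1.5)
        }
        bad <- which(abs(block - target) > tol)[1L]
        if (is.na(bad)) {
          chunks[[length(chunks) + 1L]] <- block
          break
        }
        chunks[[length(chunks) + 1L]] <- block[seq_len(bad)]
        if (tries > 200L)            # pathological tremor: force compliance
          user@tremorSd <- user@tremorSd / 2
      }
      scaleNow <- target
    }
    scales <- pmin(pmax(unlist(chunks), 0), 100)
    tms <- seq_along(scales) * dt
    ppg <- .ppgWave(subject, pressureAtScale(device, scales), tms)
    if (noise@ppgSd > 0) ppg <- ppg + rnorm(length(ppg), 0, noise@ppgSd)
    d <- device@projD0 + (device@projD100 - device@projD0) * scales / 100
    measurementFrame(timestamp = tms, area = pi * (d / 2)^2, diameter = d,
                     ppg = ppg, forceScale = scales, valid = TRUE)
  })
}

#' Render one synthetic camera frame
#'
#' A filled disk of the projection diameter implied by the force scale,
#' uniform intensity `ppg` plus per-pixel Gaussian noise, on a constant
#' dark background below the area threshold. At zero noise the frame is
#' invertible by the frame-processing stage to within 1 px of diameter and
#' 1 intensity unit of PPG.
#'
#' @param scale force scale, %.
#' @param ppg disk intensity in [20, 254].
#' @param device a [DeviceSpec-class] (projection endpoints give the
#'   diameter).
#' @param noise a [NoiseModel-class].
#' @param size frame edge length, px.
#' @param timestamp seconds.
#' @return a [CameraFrame-class].
#' @export
renderFrame <- function(scale, ppg, device = DeviceSpec(),
                        noise = NoiseModel(), size = 160L, timestamp = 0) {
  if (ppg < 20 || ppg > 254) stop("ppg must lie in [20, 254]")
  d <- device@projD0 + (device@projD100 - device@projD0) * scale / 100
  if (d >= size) stop("projection (", round(d, 1),
                      " px) does not fit in a ", size, " px frame")
  ctr <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size)
  mask <- (xs - ctr)^2 + (t(xs) - ctr)^2 <= (d / 2)^2
  px <- matrix(as.integer(round(noise@backgroundLevel)), size, size)
  vals <- rep(ppg, sum(mask))
  if (noise@pixelSd > 0) vals <- vals + rnorm(length(vals), 0, noise@pixelSd)
  px[mask] <- as.integer(pmin(pmax(round(vals), 0), 255))
  CameraFrame(px, timestamp)
}

#' Simulate a cohort of subjects
#'
#' Reference pressures are drawn from a truncated bivariate normal matched
#' to the moments of the validation cohort (SBP 116.8 +/- 20.3 mmHg, DBP
#' 73.5 +/- 12.3 mmHg, correlation 0.7; draws with SBP <= DBP + 10 are
#' rejected). Heart rate is uniform on 48--84 bpm (3--7 complete pulses per
#' 5 s window), pulse amplitude on 30--60 intensity units, baseline
#' brightness on 120--180; envelope width is coupled to pulse pressure
#' (0.75 PP), which is what renders systolic pressure identifiable from
#' the oscillogram shape. Optionally injects QC-failure subjects: zero
#' perfusion (no detectable pulse) and one fixed atypical 160/75 subject
#' (pulse pressure 85).
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param nZeroPerfusion,nHighPulsePressure number of injected QC-failure
#'   subjects (placed at the end of the cohort).
#' @param envelope envelope shape passed to every subject.
#' @return list with `subjects` (list of [SubjectTruth-class]) and
#'   `truths` (data.frame: id, sbp, dbp, mbp, hr, a_max, sigma_env,
#'   baseline, perfusion).
#' @export
simulateCohort <- function(n, seed = 1L, nZeroPerfusion = 0L,
                           nHighPulsePressure = 0L, envelope = "gaussian") {
  stopifnot(n >= 1L, nZeroPerfusion + nHighPulsePressure <= n)
  withSeed(seed, {
    mu <- c(116.8, 73.5)
    sdv <- c(20.3, 12.3)
    rho <- 0.7
    Sigma <- matrix(c(sdv[1]^2, rho * sdv[1] * sdv[2],
                      rho * sdv[1] * sdv[2], sdv[2]^2), 2L)
    draw <- function(k) MASS::mvrnorm(k, mu, Sigma)
    bp <- draw(n)
    bad <- which(bp[, 1] <= bp[, 2] + 10)
    while (length(bad)) {                    # truncation: SBP > DBP + 10
      bp[bad, ] <- draw(length(bad))
      bad <- which(bp[, 1] <= bp[, 2] + 10)
    }
    hr <- runif(n, 48, 84)
    aMax <- runif(n, 30, 60)
    baseline <- runif(n, 120, 180)
    perfusion <- rep(1, n)
    nNormal <- n - nZeroPerfusion - nHighPulsePressure
    if (nHighPulsePressure > 0L) {
      idx <- nNormal + seq_len(nHighPulsePressure)
      bp[idx, 1] <- 160
      bp[idx, 2] <- 75
    }
    if (nZeroPerfusion > 0L)
      perfusion[(n - nZeroPerfusion + 1L):n] <- 0
    subjects <- lapply(seq_len(n), function(i)
      SubjectTruth(sbp = bp[i, 1], dbp = bp[i, 2], hr = hr[i],
                   aMax = aMax[i], baseline = baseline[i],
                   perfusion = perfusion[i], envelope = envelope))
    truths <- data.frame(
      id = sprintf("S%02d", seq_len(n)), sbp = bp[, 1], dbp = bp[, 2],
      mbp = (bp[, 1] + 2 * bp[, 2]) / 3, hr = hr, a_max = aMax,
      sigma_env = vapply(subjects, function(s) s@sigmaEnv, numeric(1)),
      baseline = baseline, perfusion = perfusion)
    list(subjects = subjects, truths = truths)
  })
}
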