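## From per-level 5 s PPG segments to the 20-point subsampled oscillogram
## and the normalized 18-point feature vector.

## Forward-backward filtering with mirrored edge extension: the series is
## demeaned, reflected about both endpoints for npad samples (the MATLAB
## filtfilt convention), filtered both ways, trimmed, and re-centered.
## Plain filtfilt starts from zero state, so an un-padded constant or ramp
## would carry large boundary transients into short segments.
.zeroPhaseFilter <- function(bf, x, npad, recenter = FALSE) {
  n <- length(x)
  mu <- mean(x)
  xd <- x - mu
  npad <- max(1L, min(n - 1L, as.integer(npad)))
  pre <- 2 * xd[1L] - xd[(npad + 1L):2L]
  post <- 2 * xd[n] - xd[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(pre, xd, post))[(npad + 1L):(npad + n)]
  if (recenter) y + mu else y
}

#' Zero-phase band-pass filter for PPG segments
#'
#' Butterworth band-pass (0.5--10 Hz by default) applied forward-backward:
#' zero phase, DC fully rejected, cardiac-band gain near unity. The band
#' brackets resting-to-exercise heart rates (30--600 bpm fundamentals) and
#' removes both baseline drift from slow force changes and high-frequency
#' sensor noise.
#'
#' @param ppg numeric PPG time series sampled at `cfg@fs`.
#' @param cfg a [FilterConfig-class].
#' @return filtered series of the same length.
#' @export
bandpass <- function(ppg, cfg = FilterConfig()) {
  stopifnot(is(cfg, "FilterConfig"))
  minLen <- 3L * (2L * (2L * cfg@order) + 1L)
  if (length(ppg) <= minLen)
    stop("segment too short for stable band-pass filtering (need > ",
         minLen, " samples)")
  bf <- signal::butter(cfg@order, c(cfg@bandLo, cfg@bandHi) / (cfg@fs / 2),
                       type = "pass")
  ## demean first: the filter rejects DC in steady state, but a ~150-count
  ## baseline at the segment edges would otherwise excite boundary
  ## transients far larger than a weak pulse. The residual edge transients
  ## decay monotonically and are dropped downstream by the complete-pulse
  ## rule; mirrored padding is deliberately NOT used here, since reflected
  ## mid-phase pulses seed small oscillatory artifacts that would pass the
  ## prominence bar as spurious complete pulses.
  as.numeric(signal::filtfilt(bf, ppg - mean(ppg)))
}

#' Peak prominences with completeness flags
#'
#' Local maxima of `x` with their topographic prominence (peak height minus
#' the higher of the lowest points on the paths to the nearest higher
#' terrain on each side, or to the window edge). A peak is *complete* when
#' the lowest point on each side is an interior local minimum — i.e. both
#' flanking troughs lie inside the window, so the pulse it represents was
#' observed whole. Edge-truncated pulses are detected but flagged
#' incomplete.
#'
#' @param x numeric series.
#' @return data.frame with columns `index`, `height`, `prominence`,
#'   `leftTrough`, `rightTrough` (indices of the flanking minima used as
#'   the prominence reference), and `complete`; zero rows when `x` has no
#'   interior local maximum.
#' @export
peakProminences <- function(x) {
  n <- length(x)
  empty <- data.frame(index = integer(), height = numeric(),
                      prominence = numeric(), leftTrough = integer(),
                      rightTrough = integer(), complete = logical())
  if (n < 3L) return(empty)
  isPeak <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(isPeak)) return(empty)
  isMin <- rep(FALSE, n)
  mins <- which(x[2:(n - 1L)] < x[1:(n - 2L)] &
                x[2:(n - 1L)] < x[3:n]) + 1L
  isMin[mins] <- TRUE
  prom <- numeric(length(isPeak))
  comp <- logical(length(isPeak))
  lTr <- rTr <- integer(length(isPeak))
  for (k in seq_along(isPeak)) {
    p <- isPeak[k]
    h <- x[p]
    ## walk left to the nearest strictly higher sample (or the edge)
    l <- p - 1L
    while (l > 1L && x[l] <= h) l <- l - 1L
    lo <- if (x[l] > h) l + 1L else l
    lrange <- lo:(p - 1L)
    lArg <- lrange[which.min(x[lrange])]
    ## walk right likewise
    r <- p + 1L
    while (r < n && x[r] <= h) r <- r + 1L
    hi <- if (x[r] > h) r - 1L else r
    rrange <- (p + 1L):hi
    rArg <- rrange[which.min(x[rrange])]
    prom[k] <- h - max(x[lArg], x[rArg])
    comp[k] <- isMin[lArg] && isMin[rArg]
    lTr[k] <- lArg
    rTr[k] <- rArg
  }
  data.frame(index = isPeak, height = x[isPeak], prominence = prom,
             leftTrough = lTr, rightTrough = rTr, complete = comp)
}

#' Mean pulse amplitude of a filtered PPG segment
#'
#' Detects pulses as prominence peaks and averages their peak-to-trough
#' amplitude over *complete* pulses only. Candidate peaks must clear a
#' minimum topographic prominence of `minPromFrac` of the segment's
#' peak-to-peak range (rejects ripple) and be separated by at least
#' `minSpacingS` seconds (0.33 s, i.e. a 180 bpm ceiling); when two
#' candidates conflict the more prominent wins. Each retained pulse's
#' amplitude is its height above the higher of its two flanking troughs,
#' the minima between it and the neighbouring retained pulses (or the
#' window edge). A pulse only counts as complete when both flanking
#' troughs are interior local minima lying at least `edgeGuardS` seconds
#' inside the window: the zero-phase band-pass has not settled within
#' roughly one time constant of the 0.5 Hz edge, and troughs inside that
#' zone bias the amplitude by several percent. A segment with no complete
#' pulse returns amplitude 0, count 0 and `valid = FALSE` rather than an
#' error, so insufficient perfusion surfaces as a flag.
#'
#' @param filtered band-passed PPG segment.
#' @param fs sampling rate, Hz.
#' @param minPromFrac minimum prominence as a fraction of the segment
#'   peak-to-peak range.
#' @param minSpacingS minimum peak separation, s.
#' @param edgeGuardS exclusion margin at the window edges, s.
#' @return list with `meanAmplitude`, `count`, `valid`.
#' @export
pulseAmplitude <- function(filtered, fs, minPromFrac = 0.05,
                           minSpacingS = 0.33, edgeGuardS = 0.5) {
  pk <- peakProminences(filtered)
  if (!nrow(pk)) return(list(meanAmplitude = 0, count = 0L, valid = FALSE))
  ptp <- diff(range(filtered))
  pk <- pk[pk$prominence >= minPromFrac * ptp, , drop = FALSE]
  if (nrow(pk) > 1L) {                      # enforce minimum spacing
    keep <- logical(nrow(pk))
    minGap <- minSpacingS * fs
    for (k in order(pk$prominence, decreasing = TRUE)) {
      if (!any(keep & abs(pk$index - pk$index[k]) < minGap)) keep[k] <- TRUE
    }
    pk <- pk[keep, , drop = FALSE]
  }
  ## flanking troughs between neighbouring retained pulses
  n <- length(filtered)
  guard <- round(edgeGuardS * fs)
  idx <- sort(pk$index)
  isMin <- rep(FALSE, n)
  if (n >= 3L)
    isMin[which(filtered[2:(n - 1L)] < filtered[1:(n - 2L)] &
                filtered[2:(n - 1L)] < filtered[3:n]) + 1L] <- TRUE
  bounds <- c(1L, idx, n)
  amps <- numeric(length(idx))
  comp <- logical(length(idx))
  for (j in seq_along(idx)) {
    lreg <- bounds[j]:(idx[j] - 1L)
    rreg <- (idx[j] + 1L):bounds[j + 2L]
    lArg <- lreg[which.min(filtered[lreg])]
    rArg <- rreg[which.min(filtered[rreg])]
    amps[j] <- filtered[idx[j]] - max(filtered[lArg], filtered[rArg])
    comp[j] <- isMin[lArg] && isMin[rArg] &&
      lArg > guard && rArg <= n - guard
  }
  if (!any(comp)) return(list(meanAmplitude = 0, count = 0L, valid = FALSE))
  list(meanAmplitude = mean(amps[comp]), count = sum(comp), valid = TRUE)
}

#' Build the subsampled oscillogram from a completed session
#'
#' Band-passes each level's 5 s PPG recording and reduces it to its mean
#' complete-pulse prominence, yielding one (pressure, amplitude) point per
#' force level. Pressures come from the device model at each level's target
#' scale.
#'
#' @param session a [SessionRecord-class].
#' @param cfg a [FilterConfig-class]; its `fs` should match the protocol's.
#' @return an [Oscillogram-class].
#' @export
buildOscillogram <- function(session, cfg = NULL) {
  stopifnot(is(session, "SessionRecord"))
  if (is.null(cfg)) cfg <- FilterConfig(fs = session@config@fs)
  levels <- session@levels
  if (length(levels) != session@config@nLevels ||
      any(vapply(levels, is.null, logical(1))))
    stop("session is missing levels; a complete SessionRecord is required")
  amps <- numeric(length(levels))
  cnts <- integer(length(levels))
  for (k in seq_along(levels)) {
    filt <- bandpass(levels[[k]]@samples$ppg, cfg)
    pa <- pulseAmplitude(filt, cfg@fs)
    amps[k] <- pa$meanAmplitude
    cnts[k] <- pa$count
  }
  Oscillogram(
    levelScales = vapply(levels, function(l) l@targetScale, numeric(1)),
    pressures = vapply(levels, function(l) l@pressureMmhg, numeric(1)),
    amplitudes = amps, pulseCounts = cnts)
}

#' Reduce an oscillogram to the normalized 18-point feature vector
#'
#' Drops the lowest and highest force levels (at the lowest force the
#' finger can leave the clip; at the highest the spring bottoms out and the
#' applied force is no longer spring-determined), then min-max normalizes
#' the remaining 18 amplitudes to [0, 1] using only the retained values.
#'
#' @param osc an [Oscillogram-class] with at least 3 levels (20 in the
#'   standard protocol).
#' @return numeric vector of length `nLevels - 2` in [0, 1], ordered by
#'   ascending force level, with at least one 0 and one 1.
#' @export
selectAndNormalize <- function(osc) {
  stopifnot(is(osc, "Oscillogram"))
  a <- osc@amplitudes
  if (length(a) < 3L) stop("oscillogram has fewer than 3 levels")
  a <- a[-c(1L, length(a))]
  rng <- range(a)
  if (diff(rng) <= 0)
    stop(structure(
      list(message = "all retained amplitudes are equal; cannot normalize",
           call = NULL),
      class = c("oscilloclip_degenerate_normalization", "error",
                "condition")))
  (a - rng[1L]) / diff(rng)
}

#' Perfusion threshold from a pulse-free reference oscillogram
#'
#' Three times the median amplitude measured on a recording known to carry
#' no pulse (the simulator provides one); an oscillogram whose maximum does
#' not clear this noise-referenced bar is deemed to have insufficient
#' perfusion for interpretation.
#'
#' @param referenceAmplitudes amplitudes of a pulse-free oscillogram.
#' @return numeric(1) threshold.
#' @export
perfusionThreshold <- function(referenceAmplitudes)
  3 * median(referenceAmplitudes)

#' Quality-control exclusion rules for one subject
#'
#' A subject is excluded when (1) the reference pulse pressure
#' `ref_sbp - ref_dbp` strictly exceeds 80 mmHg (atypical pressure whose
#' oscillogram the estimator was not built for), or (2) the oscillogram's
#' maximum amplitude fails the perfusion bar (no interpretable pulse).
#' Boundary cases keep: a pulse pressure of exactly 80 is retained.
#'
#' @param osc an [Oscillogram-class].
#' @param refSbp,refDbp reference pressures, mmHg.
#' @param perfusionThr amplitude threshold, see [perfusionThreshold()];
#'   the oscillogram maximum must strictly exceed it.
#' @return list with `keep` (logical) and `reason` (`NA` when kept).
#' @export
qcExclusions <- function(osc, refSbp, refDbp, perfusionThr = 0) {
  stopifnot(is(osc, "Oscillogram"))
  if (refSbp - refDbp > 80)
    return(list(keep = FALSE, reason = "pulse pressure > 80"))
  if (!(max(osc@amplitudes) > perfusionThr))
    return(list(keep = FALSE, reason = "insufficient perfusion"))
  list(keep = TRUE, reason = NA_character_)
}
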