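## Headless re-implementation of the guided-measurement logic: 20 equally
## spaced target force scales, a +/-2% tolerance band, red -> yellow -> green
## indicator with a 2 s hold and 5 s recording, and discard-and-retry on any
## excursion while yellow or green.

#' Target force scales of the ladder
#'
#' `nLevels` scales in arithmetic progression from `scaleLo` to `scaleHi`
#' (20 levels from 5% to 95% by default, spacing 90/19).
#'
#' @param config a [ProtocolConfig-class].
#' @return numeric vector of length `nLevels`, percent.
#' @examples
#' levelTargets(ProtocolConfig())
#' @export
levelTargets <- function(config) {
  stopifnot(is(config, "ProtocolConfig"))
  seq(config@scaleLo, config@scaleHi, length.out = config@nLevels)
}

#' Fresh indicator state
#'
#' @return list with `phase` ("RED"), `tInPhase` (0) and `done` (FALSE).
#' @export
newIndicatorState <- function() list(phase = "RED", tInPhase = 0,
                                     done = FALSE)

#' Advance the guidance indicator by one sample
#'
#' The three-state machine behind the on-screen indicator. RED turns YELLOW
#' the moment the current force scale enters the closed tolerance band
#' `|current - target| <= tolerancePct` (boundary samples count as
#' in-band). YELLOW turns GREEN after `holdS` seconds continuously in-band;
#' GREEN completes (`done = TRUE`) after a further `recordS` seconds. Any
#' out-of-band sample while YELLOW or GREEN falls back to RED and discards
#' everything held so far.
#'
#' The machine is total: every (state, sample) pair has a defined
#' transition. [runSession()] implements the same semantics over a whole
#' stream; this per-sample form exists for inspection and as an independent
#' cross-check.
#'
#' @param state a state list as returned by [newIndicatorState()] or a
#'   previous call.
#' @param currentScale current force scale, %.
#' @param target target force scale, %.
#' @param dt time since the previous sample, s.
#' @param config a [ProtocolConfig-class].
#' @return the next state list.
#' @export
stepIndicator <- function(state, currentScale, target, dt, config) {
  inBand <- abs(currentScale - target) <= config@tolerancePct
  phase <- state$phase
  if (phase == "RED") {
    if (inBand) return(list(phase = "YELLOW", tInPhase = 0, done = FALSE))
    return(list(phase = "RED", tInPhase = 0, done = FALSE))
  }
  if (!inBand) return(list(phase = "RED", tInPhase = 0, done = FALSE))
  tIn <- state$tInPhase + dt
  if (phase == "YELLOW") {
    if (tIn >= config@holdS - 1e-12)
      return(list(phase = "GREEN", tInPhase = 0, done = FALSE))
    return(list(phase = "YELLOW", tInPhase = tIn, done = FALSE))
  }
  ## GREEN
  if (tIn >= config@recordS - 1e-12)
    return(list(phase = "GREEN", tInPhase = tIn, done = TRUE))
  list(phase = "GREEN", tInPhase = tIn, done = FALSE)
}

#' Error signalled when a stream ends before all levels complete
#'
#' @param levels list of completed [LevelRecording-class] objects.
#' @param levelIndex 0-based index of the level in progress.
#' @return does not return; signals a condition of class
#'   `oscilloclip_partial_session` carrying the completed levels in its
#'   `levels` field.
#' @keywords internal
partialSessionError <- function(levels, levelIndex) {
  stop(structure(
    list(message = sprintf(
      "measurement stream exhausted at level %d with %d level(s) completed",
      levelIndex, length(levels)),
      call = NULL, levels = levels),
    class = c("oscilloclip_partial_session", "error", "condition")))
}

#' Run the guided protocol over a measurement stream
#'
#' Replays a measurement stream through the level ladder: levels are
#' attempted strictly in ascending order of target scale; for each level a
#' contiguous in-band run of `holdS + recordS` seconds must be observed,
#' and every out-of-band sample after the band was entered discards the
#' attempt and increments the level's restart count. The retained samples
#' of a level are the last `recordS` seconds of its compliant hold.
#'
#' Timing is event-driven on the stream's timestamps, not wall clock: the
#' hold is satisfied at the first sample at least `holdS` seconds after
#' band entry, the recording at the first sample `holdS + recordS` seconds
#' after band entry.
#'
#' @param stream measurement data.frame (see [measurementFrame()]) with at
#'   least `timestamp_s` and `force_scale`; if `force_scale` is absent it
#'   is derived from `diameter_px` via `cal`.
#' @param cal a [Calibration-class].
#' @param config a [ProtocolConfig-class].
#' @param device a [DeviceSpec-class] used to attach a contact pressure to
#'   each level.
#' @return a [SessionRecord-class]. If the stream ends first, a condition
#'   of class `oscilloclip_partial_session` is signalled carrying the
#'   completed levels.
#' @export
runSession <- function(stream, cal, config = ProtocolConfig(),
                       device = DeviceSpec()) {
  stopifnot(is(cal, "Calibration"), is(config, "ProtocolConfig"),
            is(device, "DeviceSpec"))
  tms <- stream$timestamp_s
  scale <- stream$force_scale
  if (is.null(scale) || all(is.na(scale))) {
    if (is.null(stream$diameter_px))
      stop("stream must carry force_scale or diameter_px")
    scale <- as.numeric(forceScaleFromDiameter(cal, stream$diameter_px))
    stream$force_scale <- scale
  }
  n <- length(tms)
  targets <- levelTargets(config)
  tol <- config@tolerancePct
  total <- levelTotalS(config)
  levels <- vector("list", config@nLevels)
  i <- 1L
  for (lv in seq_len(config@nLevels)) {
    target <- targets[lv]
    restarts <- 0L
    repeat {
      if (i > n) partialSessionError(levels[seq_len(lv - 1L)], lv - 1L)
      inb <- abs(scale[i:n] - target) <= tol
      j <- which(inb)[1L]
      if (is.na(j)) partialSessionError(levels[seq_len(lv - 1L)], lv - 1L)
      j <- i + j - 1L                       # band entry (YELLOW)
      off <- which(!inb[(j - i + 1L):(n - i + 1L)])[1L]
      runEnd <- if (is.na(off)) n else j + off - 2L
      mRel <- which(tms[j:runEnd] >= tms[j] + total - 1e-9)[1L]
      if (!is.na(mRel)) {                   # level completed
        m <- j + mRel - 1L
        g <- j + max(which(tms[j:m] <= tms[m] - config@recordS + 1e-9)) - 1L
        levels[[lv]] <- new("LevelRecording",
          levelIndex = lv - 1L, targetScale = target,
          pressureMmhg = pressureAtScale(device, target),
          nRestarts = restarts, samples = stream[g:m, , drop = FALSE])
        i <- m + 1L
        break
      }
      if (is.na(off))                       # stream ended mid-hold
        partialSessionError(levels[seq_len(lv - 1L)], lv - 1L)
      restarts <- restarts + 1L             # excursion: discard and retry
      i <- runEnd + 1L
    }
  }
  lastT <- tail(levels[[config@nLevels]]@samples$timestamp_s, 1L)
  new("SessionRecord", device = device, calibration = cal, config = config,
      levels = levels, totalDuration = lastT - tms[1L])
}
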