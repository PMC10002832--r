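## Per-frame decoding of the dual-encoded signal: the projection size carries
## the applied force, the projection brightness carries the pulse.

#' A single 8-bit grayscale camera frame
#'
#' @slot pixels integer matrix of intensities in 0--255.
#' @slot timestamp numeric(1), seconds.
#' @export
setClass("CameraFrame",
  representation(pixels = "matrix", timestamp = "numeric"))

setValidity("CameraFrame", function(object) {
  px <- object@pixels
  if (!nrow(px) || !ncol(px)) return("frame must be non-empty")
  if (any(px < 0L) || any(px > 255L) || any(px != as.integer(px)))
    return("intensities must be integers in [0, 255]")
  TRUE
})

#' @param pixels integer matrix in 0--255.
#' @param timestamp seconds.
#' @return A [CameraFrame-class] object.
#' @rdname CameraFrame-class
#' @export
CameraFrame <- function(pixels, timestamp = 0) {
  storage.mode(pixels) <- "integer"
  new("CameraFrame", pixels = pixels, timestamp = timestamp)
}

setMethod("show", "CameraFrame", function(object) {
  cat("CameraFrame:", nrow(object@pixels), "x", ncol(object@pixels),
      "px, t =", object@timestamp, "s, range",
      min(object@pixels), "-", max(object@pixels), "\n")
})

#' Histogram-equalize an 8-bit frame
#'
#' Standard CDF-based equalization,
#' `v' = round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`, which flattens
#' the intensity distribution so that projections with different baseline
#' brightness (different blood volume, different skin) threshold
#' consistently. A constant frame is returned unchanged (the formula is
#' 0/0 there); rank order of distinct intensities is always preserved.
#'
#' @param frame a [CameraFrame-class] or an integer matrix in 0--255.
#' @return object of the same type with equalized intensities.
#' @export
equalizeFrame <- function(frame) {
  px <- if (is(frame, "CameraFrame")) frame@pixels else frame
  n <- length(px)
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdfMin <- cdf[which(counts > 0L)[1L]]
  if (cdfMin == n) return(frame)          # constant image: degenerate CDF
  lut <- as.integer(floor(255 * (cdf - cdfMin) / (n - cdfMin) + 0.5))
  lut[lut < 0L] <- 0L
  out <- matrix(lut[as.integer(px) + 1L], nrow = nrow(px))
  if (is(frame, "CameraFrame")) CameraFrame(out, frame@timestamp) else out
}

#' Measure the pinhole projection in an equalized frame
#'
#' The area is the count of pixels with intensity strictly above 20 (the
#' frame must already be equalized); the diameter is recovered from the
#' area of the ideal circle, `d = 2 * sqrt(area / pi)`. Zero area yields
#' zero diameter, a valid flagged result rather than an error.
#'
#' @param eqFrame equalized [CameraFrame-class] or integer matrix.
#' @return list with `area` (pixel count) and `diameter` (px).
#' @export
measureProjection <- function(eqFrame) {
  px <- if (is(eqFrame, "CameraFrame")) eqFrame@pixels else eqFrame
  area <- sum(px > .AREA_THRESHOLD)
  list(area = area, diameter = 2 * sqrt(area / pi))
}

#' Extract the PPG value from a raw frame
#'
#' The PPG sample is the mean raw intensity of the in-projection pixels
#' whose raw value lies in [20, 254] inclusive: saturated pixels (255) and
#' dark pixels (< 20) are excluded. Region membership is decided on the
#' equalized frame (intensity > 20), matching the area measurement; the
#' mean itself is taken on the raw frame, whose brightness carries the
#' blood-volume signal that equalization would distort.
#'
#' @param rawFrame raw [CameraFrame-class] or integer matrix.
#' @param eqFrame the corresponding equalized frame; computed from
#'   `rawFrame` when `NULL`.
#' @return list with `ppg` (mean intensity, `NA` when no pixel qualifies)
#'   and `valid` (logical).
#' @export
extractPPG <- function(rawFrame, eqFrame = NULL) {
  raw <- if (is(rawFrame, "CameraFrame")) rawFrame@pixels else rawFrame
  if (is.null(eqFrame)) eqFrame <- equalizeFrame(raw)
  eq <- if (is(eqFrame, "CameraFrame")) eqFrame@pixels else eqFrame
  vals <- raw[eq > .AREA_THRESHOLD]
  vals <- vals[vals >= .PPG_MIN & vals <= .PPG_MAX]
  if (!length(vals)) list(ppg = NA_real_, valid = FALSE)
  else list(ppg = mean(vals), valid = TRUE)
}

#' Decode one raw frame into a measurement row
#'
#' Runs equalization, projection measurement and PPG extraction, and (when
#' a calibration is supplied) converts the diameter to a force scale.
#'
#' @param frame a raw [CameraFrame-class].
#' @param cal optional [Calibration-class].
#' @return one-row measurement data.frame (see [measurementFrame()]).
#' @export
processFrame <- function(frame, cal = NULL) {
  stopifnot(is(frame, "CameraFrame"))
  eq <- equalizeFrame(frame)
  proj <- measureProjection(eq)
  ppg <- extractPPG(frame, eq)
  scale <- NA_real_
  if (!is.null(cal) && proj$area > 0)
    scale <- as.numeric(forceScaleFromDiameter(cal, proj$diameter))
  measurementFrame(timestamp = frame@timestamp, area = proj$area,
                   diameter = proj$diameter, ppg = ppg$ppg,
                   forceScale = scale,
                   valid = ppg$valid && proj$area > 0)
}

#' Assemble a measurement stream data.frame
#'
#' The canonical per-frame measurement container: one row per frame with
#' columns `timestamp_s`, `area_px`, `diameter_px`, `ppg`, `force_scale`,
#' `valid`. This is the CSV schema used on disk and the stream format
#' consumed by [runSession()].
#'
#' @param timestamp,area,diameter,ppg,forceScale,valid column vectors
#'   (recycled to a common length).
#' @return data.frame.
#' @export
measurementFrame <- function(timestamp, area = NA_real_,
                             diameter = NA_real_, ppg = NA_real_,
                             forceScale = NA_real_, valid = TRUE) {
  n <- length(timestamp)
  data.frame(timestamp_s = timestamp, area_px = rep_len(area, n),
             diameter_px = rep_len(diameter, n), ppg = rep_len(ppg, n),
             force_scale = rep_len(forceScale, n),
             valid = rep_len(valid, n))
}

#' Display-grade low-pass filter for the force trace
#'
#' Zero-phase Butterworth low-pass (order `order` applied forward-backward)
#' used only to de-flutter the plotted force scale: it removes the cardiac
#' ripple (>= 0.8 Hz attenuated by more than 20 dB at the 0.4 Hz default
#' cutoff) while passing slow force drift with unit DC gain. Not used in
#' the analysis path.
#'
#' @param scales force-scale time series, %.
#' @param fs sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoffHz cutoff frequency, Hz.
#' @param order Butterworth section order (effective magnitude order is
#'   doubled by the forward-backward pass).
#' @return filtered series of the same length.
#' @export
smoothForceTrace <- function(scales, fs, cutoffHz = 0.4, order = 2L) {
  if (fs <= 2 * cutoffHz) stop("fs must exceed twice the cutoff")
  minLen <- 3L * (2L * order + 1L)
  if (length(scales) <= minLen)
    stop("series too short for stable filtering (need > ", minLen,
         " samples)")
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  as.numeric(.zeroPhaseFilter(bf, scales, npad = 3 * fs / cutoffHz,
                              recenter = TRUE))
}
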