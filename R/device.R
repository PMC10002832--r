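## Forward physics of the clip and the calibrated inverse.

#' Spring force at a given compression
#'
#' Hooke's law with preload: F = preload + k * x. At the default build this
#' spans 0.1 N (resting) to 3.383 N (full 6.7 mm travel), usually quoted
#' rounded as 0.1--3.3 N.
#'
#' @param spec a [DeviceSpec-class].
#' @param x compression in mm, in `[0, travelMm]` (vectorized).
#' @return force in newtons.
#' @examples
#' forceAtCompression(DeviceSpec(), c(0, 1, 6.7))
#' @export
forceAtCompression <- function(spec, x) {
  stopifnot(is(spec, "DeviceSpec"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > spec@travelMm))
    stop("compression x must lie in [0, ", spec@travelMm, "] mm")
  spec@preloadN + spec@springK * x
}

#' Contact pressure from force over a circular contact disk
#'
#' P = F / (pi (d/2)^2), converted from pascals to mmHg (133.322 Pa/mmHg).
#' With the 10 mm contact disk, 0.1 N gives 9.5 mmHg and the rounded 3.3 N
#' ceiling gives 315 mmHg.
#'
#' @param force force in newtons (vectorized, must be >= 0).
#' @param contactDiameterMm contact disk diameter in mm.
#' @return pressure in mmHg.
#' @examples
#' pressureFromForce(c(0.1, 3.3), 10)
#' @export
pressureFromForce <- function(force, contactDiameterMm) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be finite and >= 0")
  if (contactDiameterMm <= 0) stop("contactDiameterMm must be > 0")
  areaM2 <- pi * (contactDiameterMm / 2000)^2
  (force / areaM2) * .MMHG_PER_PA
}

#' Pinhole projection diameter at a given compression
#'
#' Linear interpolation between the zero-compression and full-travel
#' projection endpoints. A similar-triangles pinhole model is nonlinear in
#' compression, but the app's own inverse works "in proportion" between its
#' two calibration endpoints, so the simulator uses the model the inverse
#' assumes; this function isolates the choice so a geometric model can be
#' swapped in.
#'
#' @param spec a [DeviceSpec-class].
#' @param x compression in mm, in `[0, travelMm]` (vectorized).
#' @return projection diameter in pixels, strictly increasing in `x`.
#' @export
projectionDiameter <- function(spec, x) {
  stopifnot(is(spec, "DeviceSpec"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > spec@travelMm))
    stop("compression x must lie in [0, ", spec@travelMm, "] mm")
  spec@projD0 + (spec@projD100 - spec@projD0) * x / spec@travelMm
}

#' Force scale from a measured projection diameter
#'
#' Linear interpolation in diameter between the session's calibration
#' endpoints: 0% at `d0`, 100% at `d100`. Diameters outside the calibrated
#' range (frame jitter past the endpoints) are clamped to [0, 100] and
#' flagged in the `"clamped"` attribute rather than rejected.
#'
#' @param cal a [Calibration-class].
#' @param d projection diameter in px (vectorized).
#' @return force scale in percent, with logical attribute `"clamped"`.
#' @examples
#' cal <- Calibration(40, 120)
#' forceScaleFromDiameter(cal, c(40, 80, 120, 130))
#' @export
forceScaleFromDiameter <- function(cal, d) {
  stopifnot(is(cal, "Calibration"))
  scale <- 100 * (d - cal@d0) / (cal@d100 - cal@d0)
  clamped <- scale < 0 | scale > 100
  scale <- pmin(pmax(scale, 0), 100)
  attr(scale, "clamped") <- clamped
  scale
}

#' Contact pressure at a target force scale
#'
#' Composes the forward chain scale -> compression -> force -> pressure so
#' every oscillogram point carries a physical pressure axis: compression is
#' `travelMm * scale / 100`, force follows [forceAtCompression()], pressure
#' follows [pressureFromForce()].
#'
#' @param spec a [DeviceSpec-class].
#' @param scale force scale in percent, in `[0, 100]` (vectorized).
#' @return pressure in mmHg.
#' @examples
#' pressureAtScale(DeviceSpec(), c(0, 50, 100))
#' @export
pressureAtScale <- function(spec, scale) {
  stopifnot(is(spec, "DeviceSpec"))
  if (any(!is.finite(scale)) || any(scale < 0) || any(scale > 100))
    stop("scale must lie in [0, 100]")
  pressureFromForce(forceAtCompression(spec, spec@travelMm * scale / 100),
                    spec@contactDiameterMm)
}
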