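# Independent oracles used across the suite. Each one is deliberately a
# different code path from the implementation it checks.

# Exhaustive pixel count above the area threshold, by explicit double loop.
bruteForceArea <- function(px) {
  n <- 0L
  for (i in seq_len(nrow(px)))
    for (j in seq_len(ncol(px)))
      if (px[i, j] > 20L) n <- n + 1L
  n
}

# Direct CDF-formula equalization via ecdf() on the flattened image.
cdfEqualize <- function(px) {
  v <- as.integer(px)
  n <- length(v)
  cdf <- ecdf(v)
  counts <- round(cdf(v) * n)   # exact integer cumulative counts
  cdfMin <- min(counts)
  if (cdfMin == n) return(px)
  out <- floor(255 * (counts - cdfMin) / (n - cdfMin) + 0.5)
  matrix(as.integer(out), nrow(px))
}

# Raster a filled disk the same way a plotting device would: pixel centers
# within radius of the center.
rasterDisk <- function(size, radius, value, background = 0L,
                       center = (size + 1) / 2) {
  px <- matrix(as.integer(background), size, size)
  for (i in seq_len(size))
    for (j in seq_len(size))
      if ((i - center)^2 + (j - center)^2 <= radius^2)
        px[i, j] <- as.integer(value)
  px
}

# Analytic squared Butterworth magnitude at frequency f (Hz): the gain of
# the forward-backward (zero-phase) filter, evaluating the transfer
# function H(z) = B(z)/A(z) at z = exp(i 2 pi f / fs) directly.
filtfiltGain <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
       sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

# Reference protocol replay: drives stepIndicator() sample by sample, the
# per-sample state machine, as an independent check of the vectorized
# runSession() scan.
replayWithIndicator <- function(stream, config) {
  targets <- levelTargets(config)
  dt <- 1 / config@fs
  lvl <- 1L
  st <- newIndicatorState()
  restarts <- integer(config@nLevels)
  completed <- list()
  buffer <- integer()
  for (i in seq_len(nrow(stream))) {
    prevPhase <- st$phase
    st <- stepIndicator(st, stream$force_scale[i], targets[lvl], dt, config)
    if (st$phase == "RED") {
      if (prevPhase != "RED") restarts[lvl] <- restarts[lvl] + 1L
      buffer <- integer()
      next
    }
    if (st$phase == "GREEN") buffer <- c(buffer, i)
    if (isTRUE(st$done)) {
      completed[[lvl]] <- list(rows = buffer, target = targets[lvl],
                               restarts = restarts[lvl])
      lvl <- lvl + 1L
      st <- newIndicatorState()
      buffer <- integer()
      if (lvl > config@nLevels) break
    }
  }
  completed
}

# Closed-form ordinary least squares through the normal equations.
olsOracle <- function(X, y) {
  Xa <- cbind(1, as.matrix(X))
  as.numeric(solve(t(Xa) %*% Xa, t(Xa) %*% y))
}

# Small compliant-but-noisy session used by several tests.
makeSession <- function(subject = SubjectTruth(120, 75),
                        user = UserModel(0, 0, 0),
                        noise = NoiseModel(pixelSd = 0, ppgSd = 0),
                        seed = 42L, protocol = ProtocolConfig()) {
  st <- simulateMeasurementStream(subject, user, DeviceSpec(), protocol,
                                  noise, seed)
  runSession(st, Calibration(40, 120), protocol)
}
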