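## On-disk formats: 8-bit grayscale PNG frames, CSV measurement streams and
## cohorts, JSON sessions and metrics. Every artifact carries schema_version,
## the seed and a config hash for reproducibility audits.

.SCHEMA_VERSION <- 1L

#' FNV-1a hash of an R object
#'
#' Deterministic 32-bit hash over the object's serialized bytes, used to
#' stamp output artifacts with the configuration that produced them.
#'
#' @param x any serializable object.
#' @return character(1), 8 hex digits.
#' @export
configHash <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30   # keep in range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Read a directory of frames
#'
#' Loads every `.png` in `dir` as an 8-bit grayscale [CameraFrame-class].
#' Filenames must carry the timestamp in milliseconds as their last
#' numeric field (e.g. `frame_000123.png` = 0.123 s); frames are returned
#' sorted by timestamp, not by lexical order. Color images are converted
#' by BT.601 luma weights (0.299, 0.587, 0.114); 16-bit images are
#' rescaled to 8-bit with a warning.
#'
#' @param dir directory path.
#' @return list of [CameraFrame-class], possibly empty.
#' @export
readFrames <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) return(list())
  stamp <- function(f) {
    b <- basename(f)
    m <- regmatches(b, gregexpr("[0-9]+", b))[[1]]
    if (!length(m)) stop("no timestamp field in frame name: ", b)
    as.numeric(tail(m, 1L)) / 1000
  }
  ts <- vapply(files, stamp, numeric(1))
  files <- files[order(ts)]
  ts <- sort(ts)
  dims <- NULL
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i], info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info) && isTRUE(info$bit.depth > 8))
      warning("16-bit frame rescaled to 8-bit: ", basename(files[i]))
    if (length(dim(img)) == 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    px <- matrix(as.integer(round(img * 255)), nrow(img))
    if (is.null(dims)) dims <- dim(px)
    else if (!identical(dims, dim(px)))
      stop("inconsistent frame dimensions at ", basename(files[i]))
    frames[[i]] <- CameraFrame(px, ts[i])
  }
  frames
}

#' Write a frame as 8-bit grayscale PNG
#'
#' @param frame a [CameraFrame-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFrame <- function(frame, path) {
  png::writePNG(frame@pixels / 255, path)
  invisible(path)
}

#' Decode a list of frames into a measurement stream
#'
#' @param frames list of [CameraFrame-class].
#' @param cal a [Calibration-class].
#' @return measurement data.frame (see [measurementFrame()]).
#' @export
framesToMeasurements <- function(frames, cal) {
  do.call(rbind, lapply(frames, processFrame, cal = cal))
}

#' Read / write a measurement stream CSV
#'
#' Columns: timestamp_s, area_px, diameter_px, ppg, force_scale, valid.
#' @param stream measurement data.frame.
#' @param path file path.
#' @return `writeMeasurements()` returns `path` invisibly;
#'   `readMeasurements()` the data.frame.
#' @export
writeMeasurements <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  df <- read.csv(path)
  need <- c("timestamp_s", "force_scale")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

.deviceToList <- function(d) list(
  spring_k = d@springK, preload_n = d@preloadN, travel_mm = d@travelMm,
  contact_diameter_mm = d@contactDiameterMm, proj_d0 = d@projD0,
  proj_d100 = d@projD100)

.deviceFromList <- function(l) DeviceSpec(
  springK = l$spring_k, preloadN = l$preload_n, travelMm = l$travel_mm,
  contactDiameterMm = l$contact_diameter_mm, projD0 = l$proj_d0,
  projD100 = l$proj_d100)

.configToList <- function(cfg) list(
  n_levels = cfg@nLevels, scale_lo = cfg@scaleLo, scale_hi = cfg@scaleHi,
  tolerance_pct = cfg@tolerancePct, hold_s = cfg@holdS,
  record_s = cfg@recordS, fs = cfg@fs)

.configFromList <- function(l) ProtocolConfig(
  nLevels = l$n_levels, scaleLo = l$scale_lo, scaleHi = l$scale_hi,
  tolerancePct = l$tolerance_pct, holdS = l$hold_s, recordS = l$record_s,
  fs = l$fs)

#' Serialize a session to JSON
#'
#' Schema: `{schema_version, device, calibration, config,
#' levels: [{index, target_scale, pressure_mmhg, n_restarts, samples}],
#' total_duration_s}`. Full numeric precision is written so that
#' `readSession(writeSession(x))` reproduces `x` field-for-field.
#'
#' @param session a [SessionRecord-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "SessionRecord"))
  obj <- list(
    schema_version = .SCHEMA_VERSION,
    device = .deviceToList(session@device),
    calibration = list(d0 = session@calibration@d0,
                       d100 = session@calibration@d100),
    config = .configToList(session@config),
    levels = lapply(session@levels, function(l) list(
      index = l@levelIndex, target_scale = l@targetScale,
      pressure_mmhg = l@pressureMmhg, n_restarts = l@nRestarts,
      samples = l@samples)),
    total_duration_s = session@totalDuration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a session from JSON
#'
#' Unknown top-level keys are preserved in the `"extra"` attribute with a
#' warning (forward compatibility); missing required keys raise a parse
#' error naming the key.
#'
#' @param path JSON path.
#' @return a [SessionRecord-class].
#' @export
readSession <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  need <- c("device", "calibration", "config", "levels",
            "total_duration_s")
  for (k in need)
    if (is.null(obj[[k]])) stop("session JSON missing required key: ", k)
  extra <- setdiff(names(obj), c(need, "schema_version"))
  lvls <- obj$levels
  mk <- function(i) {
    smp <- as.data.frame(lvls$samples[[i]])
    for (col in c("timestamp_s", "area_px", "diameter_px", "ppg",
                  "force_scale"))
      if (!is.null(smp[[col]])) smp[[col]] <- as.numeric(smp[[col]])
    new("LevelRecording",
        levelIndex = as.integer(lvls$index[i]),
        targetScale = as.numeric(lvls$target_scale[i]),
        pressureMmhg = as.numeric(lvls$pressure_mmhg[i]),
        nRestarts = as.integer(lvls$n_restarts[i]),
        samples = smp)
  }
  session <- new("SessionRecord",
    device = .deviceFromList(obj$device),
    calibration = Calibration(obj$calibration$d0, obj$calibration$d100),
    config = .configFromList(obj$config),
    levels = lapply(seq_len(nrow(lvls)), mk),
    totalDuration = as.numeric(obj$total_duration_s))
  if (length(extra)) {
    warning("session JSON carries unknown key(s), preserved: ",
            paste(extra, collapse = ", "))
    attr(session, "extra") <- obj[extra]
  }
  session
}

#' Write an oscillogram (or feature vector) CSV
#'
#' @param osc an [Oscillogram-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeOscillogram <- function(osc, path) {
  write.csv(as.data.frame(osc), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort feature table CSV
#'
#' Columns: `id`, `f01..f18`, `ref_sbp`, `ref_dbp`.
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `writeCohort()` returns `path` invisibly; `readCohort()` the
#'   validated data.frame.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- read.csv(path)
  need <- c("id", "ref_sbp", "ref_dbp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!length(.featureCols(df)))
    stop("cohort CSV carries no feature columns (f01..f18)")
  df
}
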