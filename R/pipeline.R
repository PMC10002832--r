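## End-to-end orchestration: simulate (or ingest) -> protocol -> oscillogram
## -> QC -> features -> cross-validated estimation -> metrics.

#' Full run configuration
#'
#' Bundles every stage's configuration plus the cohort size and master
#' seed. All per-subject seeds and fold assignments derive from `seed`, so
#' a run is reproducible end to end.
#'
#' @slot device a [DeviceSpec-class].
#' @slot protocol a [ProtocolConfig-class].
#' @slot filter a [FilterConfig-class].
#' @slot estimator an [EstimatorConfig-class].
#' @slot user a [UserModel-class].
#' @slot noise a [NoiseModel-class].
#' @slot nSubjects integer(1).
#' @slot nZeroPerfusion,nHighPulsePressure integer(1), injected QC-failure
#'   subjects.
#' @slot seed integer(1).
#' @export
setClass("RunConfig",
  representation(device = "DeviceSpec", protocol = "ProtocolConfig",
                 filter = "FilterConfig", estimator = "EstimatorConfig",
                 user = "UserModel", noise = "NoiseModel",
                 nSubjects = "integer", nZeroPerfusion = "integer",
                 nHighPulsePressure = "integer", seed = "integer"))

#' @param device,protocol,filter,estimator,user,noise,nSubjects,nZeroPerfusion,nHighPulsePressure,seed
#'   see slots; `filter` defaults to the protocol's sampling rate.
#' @return A [RunConfig-class] object.
#' @rdname RunConfig-class
#' @export
RunConfig <- function(device = DeviceSpec(), protocol = ProtocolConfig(),
                      filter = NULL, estimator = NULL,
                      user = UserModel(), noise = NoiseModel(),
                      nSubjects = 24L, nZeroPerfusion = 0L,
                      nHighPulsePressure = 0L, seed = 1L) {
  if (is.null(filter)) filter <- FilterConfig(fs = protocol@fs)
  if (is.null(estimator)) estimator <- EstimatorConfig(seed = seed)
  new("RunConfig", device = device, protocol = protocol, filter = filter,
      estimator = estimator, user = user, noise = noise,
      nSubjects = as.integer(nSubjects),
      nZeroPerfusion = as.integer(nZeroPerfusion),
      nHighPulsePressure = as.integer(nHighPulsePressure),
      seed = as.integer(seed))
}

#' Simulate one subject's guided session and oscillogram
#'
#' Stream simulation, protocol replay and oscillogram construction for a
#' single subject.
#'
#' @param subject a [SubjectTruth-class].
#' @param run a [RunConfig-class].
#' @param seed integer seed for this subject's stream.
#' @return list with `session` ([SessionRecord-class]) and `oscillogram`
#'   ([Oscillogram-class]).
#' @export
subjectOscillogram <- function(subject, run = RunConfig(), seed = 1L) {
  stream <- simulateMeasurementStream(subject, run@user, run@device,
                                      run@protocol, run@noise, seed)
  cal <- Calibration(run@device@projD0, run@device@projD100)
  session <- runSession(stream, cal, run@protocol, run@device)
  list(session = session, oscillogram = buildOscillogram(session,
                                                         run@filter))
}

#' Pulse-free perfusion reference for a run
#'
#' Simulates a zero-perfusion recording under the run's noise model and
#' returns the QC threshold derived from its oscillogram (see
#' [perfusionThreshold()]).
#'
#' @param run a [RunConfig-class].
#' @return numeric(1) amplitude threshold.
#' @export
runPerfusionReference <- function(run) {
  ref <- SubjectTruth(sbp = 120, dbp = 80, perfusion = 0)
  osc <- subjectOscillogram(ref, run, seed = run@seed + 90001L)$oscillogram
  perfusionThreshold(amplitudes(osc))
}

#' Run the full simulated pipeline
#'
#' Simulates a cohort, replays every subject through the guided protocol,
#' builds oscillograms, applies the QC exclusions, reduces retained
#' subjects to normalized 18-point feature vectors, runs leave-two-out
#' cross-validated estimation and computes accuracy metrics against the
#' simulated references.
#'
#' @param run a [RunConfig-class].
#' @param outDir optional directory; when given, writes `truths.csv`,
#'   `cohort.csv`, `predictions.csv` and `metrics.json`, each stamped with
#'   the seed and config hash.
#' @return list with `truths`, `oscillograms`, `qc` (data.frame id, keep,
#'   reason), `cohort` (retained feature table), `predictions`, `metrics`,
#'   `perfusionThr`, `seed`, `configHash`.
#' @export
runPipeline <- function(run = RunConfig(), outDir = NULL) {
  stopifnot(is(run, "RunConfig"))
  sim <- simulateCohort(run@nSubjects, seed = run@seed,
                        nZeroPerfusion = run@nZeroPerfusion,
                        nHighPulsePressure = run@nHighPulsePressure)
  thr <- runPerfusionReference(run)
  oscs <- vector("list", run@nSubjects)
  keep <- logical(run@nSubjects)
  reason <- rep(NA_character_, run@nSubjects)
  for (i in seq_len(run@nSubjects)) {
    oscs[[i]] <- subjectOscillogram(sim$subjects[[i]], run,
                                    seed = run@seed + 1000L * i)$oscillogram
    qc <- qcExclusions(oscs[[i]], sim$truths$sbp[i], sim$truths$dbp[i],
                       perfusionThr = thr)
    keep[i] <- qc$keep
    reason[i] <- qc$reason
  }
  if (!any(keep)) stop("no subjects after QC")
  feats <- t(vapply(oscs[keep], selectAndNormalize,
                    numeric(run@protocol@nLevels - 2L)))
  colnames(feats) <- sprintf("f%02d", seq_len(ncol(feats)))
  cohort <- data.frame(id = sim$truths$id[keep], feats,
                       ref_sbp = sim$truths$sbp[keep],
                       ref_dbp = sim$truths$dbp[keep])
  preds <- leaveTwoOutCV(cohort, run@estimator)
  metrics <- accuracyMetrics(
    preds, data.frame(sbp = cohort$ref_sbp,
                      mbp = mbpReference(cohort$ref_sbp, cohort$ref_dbp),
                      dbp = cohort$ref_dbp))
  hash <- configHash(run)
  res <- list(truths = sim$truths, oscillograms = oscs,
              qc = data.frame(id = sim$truths$id, keep = keep,
                              reason = reason),
              cohort = cohort, predictions = preds, metrics = metrics,
              perfusionThr = thr, seed = run@seed, configHash = hash)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sim$truths, file.path(outDir, "truths.csv"),
              row.names = FALSE)
    writeCohort(cohort, file.path(outDir, "cohort.csv"))
    write.csv(preds, file.path(outDir, "predictions.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(schema_version = 1L, seed = run@seed, config_hash = hash,
           n_simulated = run@nSubjects, n_retained = sum(keep),
           metrics = metrics),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
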