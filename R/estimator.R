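## SBP/MBP from the 18-point normalized oscillogram by L1-penalized linear
## regression; DBP by ordinary linear regression on the two predictions;
## evaluation by leave-two-out cross-validation with MAE/bias/Bland-Altman.

#' Evaluate with a private RNG state
#'
#' Runs `expr` under `seed` and restores the caller's RNG afterwards, so
#' seeded fold assignment never perturbs user code.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mean blood pressure from systolic and diastolic
#'
#' The standard one-third rule: MBP = 1/3 SBP + 2/3 DBP.
#'
#' @param sbp,dbp pressures in mmHg (vectorized); every `sbp` must exceed
#'   its `dbp`.
#' @return MBP in mmHg.
#' @examples
#' mbpReference(120, 60)
#' @export
mbpReference <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop("sbp must be strictly greater than dbp")
  (sbp + 2 * dbp) / 3
}

#' Fit the SBP and MBP LASSO models
#'
#' One L1-penalized linear model per target on the 18 normalized
#' oscillogram features. The penalty is chosen independently per target by
#' seeded `innerFolds`-fold cross-validation over `lambdaGrid`
#' (lambda-min rule). Features are used as-is (already in [0, 1]; no
#' re-standardization) and the intercept is unpenalized.
#'
#' @param X n x p feature matrix.
#' @param ySbp,yMbp responses, mmHg.
#' @param cfg an [EstimatorConfig-class].
#' @return list with elements `sbp` and `mbp`, each a list holding the
#'   `glmnet` `fit`, the selected `lambda`, and the nonzero-coefficient
#'   count `nonzero`.
#' @export
fitSbpMbp <- function(X, ySbp, yMbp, cfg = EstimatorConfig()) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  ## the inner CV shrinks with the training set (3-fold floor); with fewer
  ## than 3 rows no CV is possible and the least-penalized lambda is used
  nf <- max(3L, min(cfg@innerFolds, nrow(X)))
  fitOne <- function(y, seedOffset) {
    fit <- glmnet::glmnet(X, y, lambda = cfg@lambdaGrid,
                          standardize = FALSE)
    lam <- if (nrow(X) >= 3L) {
      foldid <- withSeed(cfg@seed + seedOffset,
                         sample(rep_len(seq_len(nf), nrow(X))))
      glmnet::cv.glmnet(X, y, lambda = cfg@lambdaGrid, foldid = foldid,
                        standardize = FALSE)$lambda.min
    } else min(cfg@lambdaGrid)
    beta <- as.numeric(coef(fit, s = lam))[-1L]
    list(fit = fit, lambda = lam, nonzero = sum(beta != 0))
  }
  list(sbp = fitOne(ySbp, 1001L), mbp = fitOne(yMbp, 2002L))
}

#' Fit the DBP linear model
#'
#' Ordinary least squares of reference DBP on predicted SBP and MBP. The
#' predictions supplied here should be out-of-fold predictions within the
#' training set so the DBP model never sees a subject's own fitted value.
#' (Algebraically DBP = (3 MBP - SBP) / 2 would follow from the one-third
#' rule; the free regression is nevertheless the default path, absorbing
#' the systematic error of the upstream predictions.)
#'
#' @param sbpHat,mbpHat predicted pressures, mmHg.
#' @param yDbp reference DBP, mmHg.
#' @return an `lm` fit with coefficients `(Intercept)`, `sbpHat`, `mbpHat`.
#' @export
fitDbp <- function(sbpHat, mbpHat, yDbp) {
  df <- data.frame(sbpHat = sbpHat, mbpHat = mbpHat, yDbp = yDbp)
  fit <- lm(yDbp ~ sbpHat + mbpHat, data = df)
  if (any(is.na(coef(fit))))
    stop("rank-deficient DBP design: sbpHat and mbpHat are collinear")
  fit
}

.featureCols <- function(cohort) grep("^f[0-9]+$", names(cohort), value = TRUE)

#' Leave-two-out cross-validated blood pressure estimation
#'
#' Subjects are shuffled with the configured seed and paired consecutively
#' into folds of two (24 subjects give 12 folds; an odd leftover forms a
#' final singleton fold). For each fold, SBP and MBP models are trained on
#' the remaining subjects ([fitSbpMbp()]); the DBP model is trained on
#' out-of-fold SBP/MBP predictions computed by an inner leave-two-out pass
#' within the training set at the selected penalties, preventing leakage of
#' in-sample fit quality into the DBP regression. Each subject is predicted
#' exactly once, by models that never saw its fold.
#'
#' @param cohort data.frame with columns `id`, `f01..f18` (normalized
#'   oscillogram features), `ref_sbp`, `ref_dbp`.
#' @param cfg an [EstimatorConfig-class].
#' @return data.frame with `id`, `fold`, `sbp_hat`, `mbp_hat`, `dbp_hat`
#'   (mmHg, reported to 0.1).
#' @export
leaveTwoOutCV <- function(cohort, cfg = EstimatorConfig()) {
  n <- nrow(cohort)
  if (n < 4L) stop("leave-two-out validation needs at least 4 subjects")
  featCols <- .featureCols(cohort)
  X <- as.matrix(cohort[, featCols])
  ySbp <- cohort$ref_sbp
  yDbp <- cohort$ref_dbp
  yMbp <- mbpReference(ySbp, yDbp)
  ord <- withSeed(cfg@seed, sample(n))
  foldOf <- integer(n)
  foldOf[ord] <- ceiling(seq_len(n) / 2)
  nFolds <- max(foldOf)
  out <- data.frame(id = cohort$id, fold = foldOf,
                    sbp_hat = NA_real_, mbp_hat = NA_real_,
                    dbp_hat = NA_real_)
  predAt <- function(fit, lam, rows)
    as.numeric(predict(fit, X[rows, , drop = FALSE], s = lam))
  refit <- function(rows, y, lam) {
    f <- glmnet::glmnet(X[rows, , drop = FALSE], y[rows],
                        lambda = cfg@lambdaGrid, standardize = FALSE)
    function(newRows) as.numeric(predict(f, X[newRows, , drop = FALSE],
                                         s = lam))
  }
  for (f in seq_len(nFolds)) {
    test <- which(foldOf == f)
    train <- which(foldOf != f)
    models <- fitSbpMbp(X[train, , drop = FALSE], ySbp[train], yMbp[train],
                        cfg)
    lamS <- models$sbp$lambda
    lamM <- models$mbp$lambda
    sbpHat <- predAt(models$sbp$fit, lamS, test)
    mbpHat <- predAt(models$mbp$fit, lamM, test)
    if (length(train) >= 4L) {
      ## inner leave-two-out over the training set at the chosen penalties
      innerOrd <- withSeed(cfg@seed + 7L * f, sample(train))
      innerFold <- split(innerOrd, ceiling(seq_along(innerOrd) / 2))
      sbpOof <- mbpOof <- setNames(numeric(length(train)),
                                   as.character(train))
      for (pair in innerFold) {
        sub <- setdiff(train, pair)
        if (length(sub) < 2L) {
          sbpOof[as.character(pair)] <- predAt(models$sbp$fit, lamS, pair)
          mbpOof[as.character(pair)] <- predAt(models$mbp$fit, lamM, pair)
        } else {
          sbpOof[as.character(pair)] <- refit(sub, ySbp, lamS)(pair)
          mbpOof[as.character(pair)] <- refit(sub, yMbp, lamM)(pair)
        }
      }
      dbpFit <- fitDbp(sbpOof[as.character(train)],
                       mbpOof[as.character(train)], yDbp[train])
      dbpHat <- as.numeric(predict(
        dbpFit, data.frame(sbpHat = sbpHat, mbpHat = mbpHat)))
    } else {
      ## training set too small for the free DBP regression: invert the
      ## one-third rule algebraically, DBP = (3 MBP - SBP) / 2
      dbpHat <- (3 * mbpHat - sbpHat) / 2
    }
    out$sbp_hat[test] <- sbpHat
    out$mbp_hat[test] <- mbpHat
    out$dbp_hat[test] <- dbpHat
  }
  out$sbp_hat <- round(out$sbp_hat, 1)
  out$mbp_hat <- round(out$mbp_hat, 1)
  out$dbp_hat <- round(out$dbp_hat, 1)
  out
}

#' Accuracy metrics with Bland-Altman limits of agreement
#'
#' For each target: MAE (mean absolute error) with the SD of the absolute
#' errors, bias (mean signed error, prediction minus reference), the SD of
#' the signed differences, and the Bland-Altman 95% limits of agreement
#' `bias +/- 1.96 * SD`.
#'
#' @param estimates,references either numeric vectors (one target) or
#'   data.frames sharing columns among `sbp`, `mbp`, `dbp` (suffixes
#'   `_hat` / `ref_` are tolerated).
#' @return data.frame with one row per target and columns `target`, `n`,
#'   `mae`, `mae_sd`, `bias`, `sd_diff`, `loa_lo`, `loa_hi`.
#' @examples
#' accuracyMetrics(c(104, 114), c(100, 120))
#' @export
accuracyMetrics <- function(estimates, references) {
  oneTarget <- function(pred, ref, label) {
    if (length(pred) != length(ref))
      stop("estimates and references differ in length for ", label)
    if (!length(pred)) stop("empty input for ", label)
    d <- pred - ref
    data.frame(target = label, n = length(d), mae = mean(abs(d)),
               mae_sd = sd(abs(d)), bias = mean(d), sd_diff = sd(d),
               loa_lo = mean(d) - 1.96 * sd(d),
               loa_hi = mean(d) + 1.96 * sd(d))
  }
  if (is.numeric(estimates) && is.numeric(references))
    return(oneTarget(estimates, references, "value"))
  pick <- function(df, tgt) {
    cand <- c(tgt, paste0(tgt, "_hat"), paste0("ref_", tgt))
    hit <- cand[cand %in% names(df)][1L]
    if (is.na(hit)) NULL else df[[hit]]
  }
  rows <- lapply(c("sbp", "mbp", "dbp"), function(tgt) {
    p <- pick(estimates, tgt)
    r <- pick(references, tgt)
    if (is.null(p) || is.null(r)) return(NULL)
    oneTarget(p, r, toupper(tgt))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no shared targets between estimates and references")
  do.call(rbind, rows)
}
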