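test_that("mean BP follows the one-third rule", {
  expect_equal(mbpReference(120, 60), 80)
  expect_equal(mbpReference(150, 75), 100)
  expect_error(mbpReference(90, 90), "strictly greater")
})

test_that("heavy L1 penalty collapses to the training mean", {
  set.seed(3)
  X <- matrix(runif(24 * 18), 24)
  y <- rnorm(24, 120, 15)
  cfg <- EstimatorConfig(lambdaGrid = c(1e9, 1e8, 1e7), seed = 4)
  fits <- fitSbpMbp(X, y, y - 30, cfg)
  expect_equal(fits$sbp$nonzero, 0)
  pred <- as.numeric(predict(fits$sbp$fit, X, s = fits$sbp$lambda))
  expect_equal(pred, rep(mean(y), 24), tolerance = 1e-8)
})

test_that("a sparse signal is recovered and matches the OLS oracle", {
  set.seed(8)
  X <- matrix(runif(400 * 18), 400)
  y <- 10 * X[, 5] + 100
  cfg <- EstimatorConfig(lambdaGrid = c(1e-3, 1e-4, 1e-5), seed = 1)
  fits <- fitSbpMbp(X, y, y, cfg)
  beta <- as.numeric(coef(fits$sbp$fit, s = fits$sbp$lambda))
  expect_equal(beta[6], 10, tolerance = 0.01)
  expect_lt(max(abs(beta[-c(1, 6)])), 0.01)
  # at negligible penalty the fit agrees with closed-form least squares
  ols <- olsOracle(X[, 5, drop = FALSE], y)
  expect_equal(beta[1], ols[1], tolerance = 0.01)
})

test_that("duplicated rows equal a count-weighted fit", {
  set.seed(12)
  X <- matrix(runif(12 * 18), 12)
  y <- 80 + 30 * X[, 2] - 10 * X[, 9] + rnorm(12, 0, 1)
  lam <- 0.05
  dup <- glmnet::glmnet(X[rep(1:12, each = 2), ], rep(y, each = 2),
                        lambda = lam, standardize = FALSE)
  wtd <- glmnet::glmnet(X, y, weights = rep(2, 12), lambda = lam,
                        standardize = FALSE)
  expect_equal(as.numeric(coef(dup)), as.numeric(coef(wtd)),
               tolerance = 1e-6)
})

test_that("the DBP regression inverts the one-third rule exactly", {
  set.seed(2)
  mbp <- runif(30, 70, 110)
  sbp <- mbp + runif(30, 10, 35)
  dbp <- (3 * mbp - sbp) / 2
  fit <- fitDbp(sbp, mbp, dbp)
  expect_equal(unname(coef(fit)), c(0, -0.5, 1.5), tolerance = 1e-9)
  # constant response: zero slopes, intercept at the mean
  fitC <- fitDbp(sbp, mbp, rep(70, 30))
  expect_equal(unname(coef(fitC)), c(70, 0, 0), tolerance = 1e-9)
  # noisy cohort: coefficients equal the closed-form OLS solution
  dbpN <- dbp + rnorm(30, 0, 2)
  fitN <- fitDbp(sbp, mbp, dbpN)
  expect_equal(unname(coef(fitN)), olsOracle(cbind(sbp, mbp), dbpN),
               tolerance = 1e-9)
  # collinear predictors are rejected
  expect_error(fitDbp(sbp, 2 * sbp, dbp), "collinear")
})

makeCohort <- function(n, seed = 1) {
  set.seed(seed)
  sbp <- rnorm(n, 117, 15)
  dbp <- sbp - runif(n, 25, 55)
  map <- (sbp + 2 * dbp) / 3
  p <- pressureAtScale(DeviceSpec(), seq(5, 95, length.out = 20))[2:19]
  X <- t(vapply(seq_len(n), function(i) {
    a <- exp(-(p - map[i])^2 / (2 * (0.75 * (sbp[i] - dbp[i]))^2))
    (a - min(a)) / diff(range(a))
  }, numeric(18)))
  colnames(X) <- sprintf("f%02d", 1:18)
  data.frame(id = sprintf("S%02d", 1:n), X, ref_sbp = sbp, ref_dbp = dbp)
}

test_that("leave-two-out partitions pair every subject exactly once", {
  cohort <- makeCohort(24)
  cfg <- EstimatorConfig(seed = 5)
  preds <- leaveTwoOutCV(cohort, cfg)
  expect_equal(nrow(preds), 24)
  expect_equal(length(unique(preds$fold)), 12)
  expect_true(all(table(preds$fold) == 2))
  expect_true(all(is.finite(preds$sbp_hat)))
  # same seed, same folds and predictions; different seed, different folds
  expect_identical(preds, leaveTwoOutCV(cohort, cfg))
  preds2 <- leaveTwoOutCV(cohort, EstimatorConfig(seed = 6))
  expect_false(identical(preds$fold, preds2$fold))
  # small cohorts: the inner CV shrinks with the training set
  expect_equal(length(unique(suppressWarnings(
    leaveTwoOutCV(makeCohort(4), cfg))$fold)), 2)
  expect_error(leaveTwoOutCV(makeCohort(3), cfg), "at least 4")
})

test_that("with an infinite penalty CV predictions are training-fold means", {
  cohort <- makeCohort(8, seed = 3)
  cfg <- EstimatorConfig(lambdaGrid = c(1e9, 1e8), seed = 2)
  preds <- suppressWarnings(leaveTwoOutCV(cohort, cfg))
  for (f in unique(preds$fold)) {
    trainMean <- mean(cohort$ref_sbp[preds$fold != f])
    expect_equal(preds$sbp_hat[preds$fold == f],
                 rep(round(trainMean, 1), 2))
  }
})

test_that("accuracy metrics compute MAE, bias and limits of agreement", {
  m <- accuracyMetrics(c(104, 114), c(100, 120))
  expect_equal(m$bias, -1)
  expect_equal(m$mae, 5)
  # identity and constant offset
  expect_equal(accuracyMetrics(c(1, 2, 3), c(1, 2, 3))$mae, 0)
  off <- accuracyMetrics(c(3, 4, 5), c(1, 2, 3))
  expect_equal(off$mae, 2)
  expect_equal(off$bias, 2)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_lo, off$loa_hi), c(2, 2))
  # LoA formula on a known spread
  d <- c(-2, 0, 2)
  sp <- accuracyMetrics(c(98, 100, 102), c(100, 100, 100))
  expect_equal(sp$loa_hi, mean(d) + 1.96 * sd(d))
  # data.frame interface picks matched targets
  est <- data.frame(sbp_hat = c(120, 130), dbp_hat = c(80, 82))
  ref <- data.frame(sbp = c(118, 131), dbp = c(79, 85))
  mm <- accuracyMetrics(est, ref)
  expect_equal(mm$target, c("SBP", "DBP"))
  expect_error(accuracyMetrics(1:3, 1:4), "length")
})
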