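test_that("F1 and recall follow the confusion-count formulas with 0/0 -> 0", {
  expect_equal(f1AndRecall(2, 0, 0), list(f1 = 1, recall = 1))
  expect_equal(f1AndRecall(1, 1, 1), list(f1 = 0.5, recall = 0.5))
  expect_equal(f1AndRecall(0, 0, 3), list(f1 = 0, recall = 0))
  expect_equal(f1AndRecall(0, 0, 0), list(f1 = 0, recall = 0))
  # oracle: direct arithmetic at P = 2/3, R = 1/2
  expect_equal(f1AndRecall(2, 1, 2)$f1, 2 * (2/3) * (1/2) / (2/3 + 1/2))
  expect_error(f1AndRecall(-1, 0, 0), "non-negative")
})

test_that("the nu-property bounds hold on one-class training runs", {
  set.seed(19)
  X <- matrix(rnorm(200 * 2), 200, 2)
  for (nu in c(0.1, 0.3)) {
    model <- trainOneClass(X, ocsvmSpec(nu = nu))
    expect_lte(model@trainOutlierFraction, nu + 0.05)
    expect_gte(model@svFraction, nu - 0.05)
  }
  expect_error(trainOneClass(X[1, , drop = FALSE]), "at least 2")
})

test_that("a far outlier is scored out-of-class and flagged present", {
  set.seed(20)
  X <- matrix(rnorm(150 * 3), 150, 3)
  model <- trainOneClass(X, ocsvmSpec(nu = 0.1))
  far <- matrix(100, 1, 3)
  expect_lt(decisionScores(model, far), 0)
  expect_equal(predictDescriptor(model, far), 1L)
  # on the training rows at most ~nu are flagged present
  expect_lte(mean(predictDescriptor(model, X)), 0.1 + 0.05)
  expect_error(decisionScores(model, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("duplicating the training rows leaves the outlier fraction stable", {
  set.seed(23)
  X <- matrix(rnorm(120 * 2), 120, 2)
  m1 <- trainOneClass(X, ocsvmSpec(nu = 0.2))
  m2 <- trainOneClass(rbind(X, X), ocsvmSpec(nu = 0.2))
  expect_lt(abs(m1@trainOutlierFraction - m2@trainOutlierFraction), 0.05)
})

test_that("stratified folds are reproducible and spread positives", {
  y <- c(rep(1L, 9), rep(0L, 91))
  f1 <- smellbench:::stratifiedFolds(y, 10, 3, seed = 5)
  f2 <- smellbench:::stratifiedFolds(y, 10, 3, seed = 5)
  expect_identical(f1, f2)
  for (r in 1:3) {
    posPerFold <- table(factor(f1[y == 1L, r], levels = 1:10))
    expect_lte(max(posPerFold) - min(posPerFold), 1)
  }
})

test_that("repeated CV is seeded-reproducible and retains fold values", {
  co <- makeCohort(n = 60, nDesc = 8, seed = 2)
  pp <- preprocessFeatures(co$features$enose)
  r1 <- suppressMessages(evaluateRepeatedCV(pp$scores, co$labels, "ocsvm",
    k = 5, repeats = 2, seed = 4))
  r2 <- suppressMessages(evaluateRepeatedCV(pp$scores, co$labels, "ocsvm",
    k = 5, repeats = 2, seed = 4))
  expect_identical(foldF1(r1), foldF1(r2))
  expect_equal(ncol(foldF1(r1)), 10)       # k * repeats fold values retained
  expect_true(all(foldF1(r1) >= 0 & foldF1(r1) <= 1))
})

test_that("fold metrics agree with brute-force confusion recomputation", {
  co <- makeCohort(n = 50, nDesc = 6, seed = 8)
  pp <- preprocessFeatures(co$features$enose)
  res <- suppressMessages(evaluateRepeatedCV(pp$scores, co$labels, "ocsvm",
    k = 5, repeats = 2, seed = 1))
  cnt <- foldCounts(res)
  for (d in seq_len(nrow(foldF1(res)))) {
    for (j in seq_len(ncol(foldF1(res)))) {
      tp <- cnt[d, j, "tp"]; fp <- cnt[d, j, "fp"]; fn <- cnt[d, j, "fn"]
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(foldF1(res)[d, j], f1)
      expect_equal(foldRecall(res)[d, j], rec)
    }
  }
})

test_that("targets without both classes are excluded with a message", {
  co <- makeCohort(n = 40, nDesc = 5, seed = 3)
  Y <- labelMatrix(co$labels)
  Y[, 2] <- 0L
  Y[, 4] <- 1L
  pp <- preprocessFeatures(co$features$enose)
  expect_message(
    res <- evaluateRepeatedCV(pp$scores, DescriptorMatrix(Y), "ocsvm",
      k = 4, repeats = 1, seed = 1),
    "odor02.*odor04")
  expect_equal(nrow(foldF1(res)), 3)
  expect_setequal(res@excluded, c("odor02", "odor04"))
})

test_that("all descriptors in give one result each; k is validated", {
  co <- makeCohort(n = 60, nDesc = 10, seed = 5)
  pp <- preprocessFeatures(co$features$enose)
  res <- suppressMessages(evaluateRepeatedCV(pp$scores, co$labels, "ocsvm",
    k = 5, repeats = 1, seed = 2))
  expect_equal(nrow(foldF1(res)) + length(res@excluded), 10)
  expect_error(evaluateRepeatedCV(pp$scores, co$labels, k = 100), "exceeds")
  expect_error(evaluateRepeatedCV(pp$scores, co$labels, k = 1), "at least 2")
})

test_that("strongly separable synthetic data is predicted nearly perfectly", {
  # two well-separated clusters; descriptor present iff in the displaced one.
  # n is large enough that the one-class frontier generalizes: with few
  # training rows an OCSVM flags held-out in-class points at well above nu.
  set.seed(44)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3, sd = 0.3), n, 3) + 8 * y
  rownames(X) <- sprintf("m%03d", 1:n)
  Y <- matrix(y, ncol = 1, dimnames = list(rownames(X), "target"))
  res <- evaluateRepeatedCV(X, Y, "ocsvm", spec = ocsvmSpec(nu = 0.01, gamma = 0.1),
    k = 5, repeats = 2, seed = 6)
  expect_gte(mean(meanF1(res)), 0.95)
  resb <- evaluateRepeatedCV(X, Y, "binary_svm", k = 5, repeats = 2, seed = 6)
  expect_gte(mean(meanF1(resb)), 0.95)
})

test_that("mean F1 responds monotonically to the planted signal strength", {
  f1At <- function(sig) {
    co <- makeCohort(n = 120, nDesc = 15, signal = sig, seed = 27)
    pp <- preprocessFeatures(co$features$enose)
    res <- suppressMessages(evaluateRepeatedCV(pp$scores, co$labels, "ocsvm",
      k = 5, repeats = 1, seed = 27))
    meanF1(res)
  }
  f0 <- f1At(0); f1 <- f1At(1); f3 <- f1At(3)
  common01 <- intersect(names(f0), names(f1))
  common13 <- intersect(names(f1), names(f3))
  expect_lt(mean(f0[common01]), mean(f1[common01]))
  p01 <- stats::t.test(f1[common01], f0[common01], paired = TRUE,
    alternative = "greater")$p.value
  p13 <- stats::t.test(f3[common13], f1[common13], paired = TRUE,
    alternative = "greater")$p.value
  expect_lt(p01, 0.05)
  expect_lt(p13, 0.05)
})

test_that("hyperparameter search picks the exhaustive-grid argmax with tie rules", {
  co <- makeCohort(n = 50, nDesc = 4, seed = 9)
  pp <- preprocessFeatures(co$features$enose)
  grid <- list(ocsvmSpec(nu = 0.1, gamma = 0.1), ocsvmSpec(nu = 0.3, gamma = 1))
  best <- searchHyperparameters(pp$scores, co$labels, grid, k = 4,
    repeats = 1, seed = 3)
  # oracle: evaluate each grid point independently and compare
  f1s <- sapply(grid, function(spec) meanF1(suppressMessages(
    evaluateRepeatedCV(pp$scores, co$labels, "ocsvm", spec = spec,
      k = 4, repeats = 1, seed = 3))))
  for (d in names(best)) {
    expect_equal(best[[d]], grid[[which.max(f1s[d, ])]])
  }
  # a one-spec grid returns that spec
  one <- searchHyperparameters(pp$scores, co$labels, list(ocsvmSpec(nu = 0.2)),
    k = 4, repeats = 1, seed = 3)
  expect_equal(one[[1]]$nu, 0.2)
  expect_error(searchHyperparameters(pp$scores, co$labels, list()), "non-empty")
})

test_that("ties in the search are broken toward smaller nu then smaller gamma", {
  # constant features make every spec equally (un)informative
  X <- matrix(0.5, 30, 3, dimnames = list(sprintf("m%02d", 1:30), NULL))
  X <- X + matrix(rnorm(90, sd = 1e-9), 30, 3)
  y <- matrix(rep(c(0L, 1L), 15), ncol = 1,
    dimnames = list(rownames(X), "t"))
  grid <- list(ocsvmSpec(nu = 0.5, gamma = 1), ocsvmSpec(nu = 0.1, gamma = 1),
    ocsvmSpec(nu = 0.1, gamma = 0.01))
  best <- searchHyperparameters(X, y, grid, k = 3, repeats = 1, seed = 2)
  f1 <- attr(best, "f1")
  if (length(unique(f1[1, ])) == 1L) {
    expect_equal(best[[1]]$nu, 0.1)
    expect_equal(best[[1]]$gamma, 0.01)
  }
})

test_that("paired comparison matches the closed form and the t oracle", {
  d <- c(0.1, 0.1, 0.1, -0.1)
  cmp <- compareFeatureSets(d, rep(0, 4))
  expect_equal(cmp@statistic, 1.0, tolerance = 1e-12)
  expect_equal(cmp@pValue, 2 * stats::pt(-1, 3), tolerance = 1e-12)
  expect_equal(round(cmp@pValue, 3), 0.391)

  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- runif(n); b <- runif(n)
    cmp <- compareFeatureSets(a, b)
    oracle <- stats::t.test(a, b, paired = TRUE)
    expect_equal(cmp@statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(cmp@pValue, oracle$p.value, tolerance = 1e-10)
    expect_equal(cmp@nPairs, n)
  }
})

test_that("degenerate comparisons are flagged, not NaN", {
  cmp <- compareFeatureSets(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_true(cmp@degenerate)
  expect_true(is.na(cmp@pValue))
  cmp2 <- compareFeatureSets(c(0.5, 0.6), c(0.4, 0.5))   # constant nonzero diff
  expect_true(cmp2@degenerate)
  expect_equal(cmp2@pValue, 0)
  expect_error(compareFeatureSets(0.5, 0.4), "at least 2")
  expect_error(compareFeatureSets(c(a = 1, b = 0), c(b = 0, a = 1)),
    "same order")
})
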