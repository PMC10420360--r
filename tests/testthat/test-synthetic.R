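test_that("generators are deterministic under a fixed seed", {
  truth <- traceGroundTruth(rep(30000, 4), c(80, 20, 50, 5), onsetIndex = 50,
    noiseSd = 2)
  t1 <- generateTraces(3, truth, nReplicates = 2, seed = 7, nTimepoints = 120)
  t2 <- generateTraces(3, truth, nReplicates = 2, seed = 7, nTimepoints = 120)
  expect_identical(t1, t2)

  c1 <- makeCohort(n = 20, nDesc = 6, seed = 3)
  c2 <- makeCohort(n = 20, nDesc = 6, seed = 3)
  expect_identical(labelMatrix(c1$labels), labelMatrix(c2$labels))
  expect_identical(featureMatrix(c1$features$enose), featureMatrix(c2$features$enose))

  g <- plantedGrouping(10, 2)
  expect_identical(generateEmbeddingFixture(g, 16, 5, seed = 1),
    generateEmbeddingFixture(g, 16, 5, seed = 1))
  expect_identical(generateSpectra(5, 30, 0.3, seed = 4),
    generateSpectra(5, 30, 0.3, seed = 4))
})

test_that("noiseless traces carry exactly the planted magnitudes", {
  mags <- c(80, 0, 33.5, 120)
  truth <- traceGroundTruth(rep(30000, 4), mags, onsetIndex = 50, noiseSd = 0)
  traces <- generateTraces(2, truth, nReplicates = 3, seed = 1, nTimepoints = 300)
  for (reps in traces) for (tr in reps) {
    expect_identical(unname(extractSmellVector(tr)), mags)
  }
})

test_that("replicates are independent and noise truth is validated", {
  truth <- traceGroundTruth(rep(1000, 2), c(10, 20), onsetIndex = 20, noiseSd = 1)
  reps <- generateTraces(1, truth, nReplicates = 3, seed = 2, nTimepoints = 60)[[1]]
  expect_length(reps, 3)
  expect_false(identical(traceMatrix(reps[[1]]), traceMatrix(reps[[2]])))
  expect_error(traceGroundTruth(1000, 10, 20, noiseSd = -1), "non-negative")
  expect_error(traceGroundTruth(1000, -5, 20), "non-negative")
})

test_that("zero signal strength decouples features from labels", {
  co <- makeCohort(n = 500, nDesc = 10, signal = 0, seed = 21)
  X <- featureMatrix(co$features$enose)
  Y <- labelMatrix(co$labels)
  # average |correlation| between any feature and any label stays near zero
  r <- abs(stats::cor(X[, 1:10], Y))
  expect_lt(max(r), 0.17)
  expect_lt(mean(r), 0.05)
})

test_that("default prevalences follow the long-tailed study profile", {
  p <- defaultPrevalences(93)
  counts <- round(p * 114)
  expect_equal(counts[1:2], c(55, 52))
  expect_true(all(diff(p) <= 0))
  expect_gt(mean(counts < 12), 0.5)         # most descriptors below 12 positives
  expect_true(all(p > 0 & p < 1))
})

test_that("cohort labels realize the long-tailed profile at study scale", {
  co <- makeCohort(n = 114, nDesc = 93, signal = 1, seed = 13)
  pos <- colSums(labelMatrix(co$labels))
  expect_gt(mean(pos < 12), 0.5)
  expect_gt(max(pos), 35)
  expect_error(generateCohort(1, co$vocab,
    cohortGroundTruth(defaultPrevalences(93))), "at least 2")
})

test_that("embedding fixtures have unit norm and planted separation", {
  g <- plantedGrouping(24, 3)
  emb <- generateEmbeddingFixture(g, dim = 50, separation = 20, seed = 5)
  expect_equal(unname(sqrt(rowSums(emb^2))), rep(1, 24), tolerance = 1e-12)
  s <- similarityMatrix(emb)
  within <- s[outer(g, g, "==") & upper.tri(s)]
  between <- s[outer(g, g, "!=") & upper.tri(s)]
  expect_gt(min(within), max(between))

  emb0 <- generateEmbeddingFixture(g, dim = 50, separation = 0, seed = 5)
  s0 <- similarityMatrix(emb0)
  w0 <- s0[outer(g, g, "==") & upper.tri(s0)]
  b0 <- s0[outer(g, g, "!=") & upper.tri(s0)]
  expect_lt(abs(mean(w0) - mean(b0)), 0.1)
  expect_error(generateEmbeddingFixture(g, dim = 1), "at least 2")
})

test_that("spectra respect sparsity, coverage and validity", {
  sp <- generateSpectra(10, 50, sparsity = 1, seed = 3)
  expect_true(all(vapply(sp, nrow, 0L) == 50))
  sp <- generateSpectra(20, 60, sparsity = 0.2, seed = 3)
  expect_true(all(vapply(sp, nrow, 0L) == ceiling(0.2 * 60)))
  expect_true(all(unlist(lapply(sp, `[[`, "intensity")) >= 0))
  # cohort has 20*12 = 240 >= 60 peak slots: union covers every configured bin
  expect_setequal(unique(unlist(lapply(sp, `[[`, "mz"))), 1:60)
  expect_error(generateSpectra(3, 0), "at least 1")
  expect_error(generateSpectra(3, 10, sparsity = 0), "\\(0, 1]")
})
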