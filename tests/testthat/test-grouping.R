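test_that("cosine similarity matches hand computation and the dot oracle", {
  expect_equal(cosineSimilarity(c(3, 4), c(3, 4)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1), c(1, 0)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(round(cosineSimilarity(c(1, 1), c(1, 0)), 8), 0.70710678)
  expect_error(cosineSimilarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosineSimilarity(1:2, 1:3), "equal dimension")

  set.seed(14)
  for (i in 1:100) {
    u <- rnorm(6); v <- rnorm(6)
    oracle <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
    expect_equal(cosineSimilarity(u, v), oracle, tolerance = 1e-12)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  emb <- generateEmbeddingFixture(plantedGrouping(12, 3), dim = 20,
    separation = 4, seed = 2)
  s <- similarityMatrix(emb)
  expect_equal(max(abs(s - t(s))), 0)
  expect_equal(unname(diag(s)), rep(1, 12))
  expect_true(all(s >= -1 - 1e-12 & s <= 1 + 1e-12))
  # off-diagonal entries match the pairwise function
  expect_equal(s[2, 5], cosineSimilarity(emb[2, ], emb[5, ]), tolerance = 1e-12)
})

test_that("descriptor clustering recovers a planted partition", {
  g <- plantedGrouping(20, 2)
  emb <- generateEmbeddingFixture(g, dim = 30, separation = 10, seed = 6)
  grouping <- clusterDescriptors(similarityMatrix(emb), 2)
  expect_equal(pairAgreement(clusterAssignments(grouping), g), 1)
})

test_that("descriptor clustering handles edge cuts and validates input", {
  g <- plantedGrouping(8, 2)
  emb <- generateEmbeddingFixture(g, dim = 10, separation = 5, seed = 3)
  s <- similarityMatrix(emb)
  singletons <- clusterDescriptors(s, 8)
  expect_equal(nClusters(singletons), 8L)
  expect_equal(sort(unname(clusterAssignments(singletons))), 1:8)
  expect_error(clusterDescriptors(s, 0), "\\[1, vocabulary size]")
  expect_error(clusterDescriptors(s, 9), "\\[1, vocabulary size]")
  bad <- s; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(clusterDescriptors(bad, 2), "symmetric")
})

test_that("a 93-word vocabulary cut at 6 yields 6 non-empty size-ordered groups", {
  g <- plantedGrouping(93, 6)
  emb <- generateEmbeddingFixture(g, dim = 60, separation = 8, seed = 10)
  grouping <- clusterDescriptors(similarityMatrix(emb), 6)
  sizes <- table(clusterAssignments(grouping))
  expect_equal(nClusters(grouping), 6L)
  expect_true(all(sizes > 0))
  expect_true(all(diff(as.integer(sizes)) <= 0))   # cluster 1 is the largest
  expect_equal(pairAgreement(clusterAssignments(grouping), g), 1)
})

test_that("clustering is invariant to vocabulary order", {
  g <- plantedGrouping(15, 3)
  emb <- generateEmbeddingFixture(g, dim = 25, separation = 7, seed = 4)
  s <- similarityMatrix(emb)
  a <- clusterAssignments(clusterDescriptors(s, 3))
  perm <- sample(15)
  b <- clusterAssignments(clusterDescriptors(s[perm, perm], 3))
  expect_equal(pairAgreement(a[names(b)], b), 1)
})

test_that("multi-word descriptors embed as token means, OOV raises", {
  emb <- rbind(sweet = c(1, 0), orange = c(0, 1))
  v <- embedDescriptors(c("sweet", "sweet orange", "sweet-orange"), emb)
  expect_equal(unname(v[2, ]), c(0.5, 0.5))
  expect_equal(unname(v[3, ]), c(0.5, 0.5))
  expect_error(embedDescriptors("umami", emb), "umami")
})

test_that("group targets are the OR over member descriptors", {
  Y <- matrix(c(0, 1, 0,   0, 0, 0,   1, 0, 0), nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  grouping <- new("DescriptorGrouping",
    assignment = c(a = 1L, b = 1L, c = 2L), nClusters = 2L)
  G <- buildGroupTargets(DescriptorMatrix(Y), grouping)
  expect_equal(unname(labelMatrix(G)[1, ]), c(1L, 0L))   # sample with {b}
  expect_equal(unname(labelMatrix(G)[2, ]), c(0L, 0L))   # no descriptors
  expect_equal(unname(labelMatrix(G)[3, ]), c(1L, 0L))
  badGrouping <- new("DescriptorGrouping", assignment = c(a = 1L, b = 2L),
    nClusters = 2L)
  expect_error(buildGroupTargets(DescriptorMatrix(Y), badGrouping), "c")
})

test_that("group positive counts respect the OR bounds on every dataset", {
  for (seed in 1:3) {
    co <- makeCohort(n = 70, nDesc = 12, seed = seed,
      grouping = rep_len(1:3, 12))
    g <- new("DescriptorGrouping",
      assignment = stats::setNames(rep_len(1:3, 12), co$vocab), nClusters = 3L)
    G <- labelMatrix(buildGroupTargets(co$labels, g))
    Y <- labelMatrix(co$labels)
    for (cl in 1:3) {
      members <- co$vocab[rep_len(1:3, 12) == cl]
      memberPos <- colSums(Y[, members, drop = FALSE])
      expect_gte(sum(G[, cl]), max(memberPos))
      expect_lte(sum(G[, cl]), sum(memberPos))
    }
  }
})

test_that("separable groups are predicted well and ROC rates computed", {
  set.seed(55)
  n <- 80
  g1 <- rep(c(0L, 1L), each = n / 2)
  g2 <- rep(c(1L, 0L, 1L, 0L), each = n / 4)
  X <- cbind(8 * g1, 8 * g2) + matrix(rnorm(2 * n, sd = 0.2), n, 2)
  rownames(X) <- sprintf("m%02d", 1:n)
  G <- DescriptorMatrix(matrix(c(g1, g2), ncol = 2,
    dimnames = list(rownames(X), c("group1", "group2"))))
  ev <- evaluateGroups(X, G, "binary_svm", k = 5, repeats = 2, seed = 3)
  expect_gte(min(ev@rates$tpr), 0.95)
  expect_lte(max(ev@rates$fpr), 0.05)
  expect_gte(min(ev@rates$f1), 0.95)
})

test_that("permuted group targets fall near the ROC chance diagonal", {
  set.seed(56)
  n <- 80
  g1 <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(8 * g1, rnorm(n)) + matrix(rnorm(2 * n, sd = 0.2), n, 2)
  rownames(X) <- sprintf("m%02d", 1:n)
  perm <- sample(n)
  G <- DescriptorMatrix(matrix(g1[perm], ncol = 1,
    dimnames = list(rownames(X), "group1")))
  ev <- evaluateGroups(X, G, "binary_svm", k = 5, repeats = 2, seed = 3)
  expect_lt(abs(ev@rates$tpr - ev@rates$fpr), 0.25)
})

test_that("groups positive for every sample are excluded", {
  co <- makeCohort(n = 40, nDesc = 6, seed = 12)
  G <- labelMatrix(co$labels)[, 1:2]
  G[, 1] <- 1L
  colnames(G) <- c("group1", "group2")
  expect_message(
    ev <- evaluateGroups(featureMatrix(co$features$enose), DescriptorMatrix(G),
      k = 4, repeats = 1, seed = 2),
    "group1")
  expect_equal(ev@rates$group, "group2")
})
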