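# Shared fixture builders. Everything is generated in code at test time.

# A small multimodal cohort with coupled labels.
makeCohort <- function(n = 80, nDesc = 12, signal = 3, seed = 11,
                       grouping = NULL, noiseSd = 0.1) {
  vocab <- sprintf("odor%02d", seq_len(nDesc))
  truth <- cohortGroundTruth(defaultPrevalences(nDesc), signalStrength = signal,
    grouping = grouping, noiseSd = noiseSd, seed = seed)
  c(generateCohort(n, vocab, truth, seed = seed), list(vocab = vocab))
}

# Three well-separated Gaussian blobs in 2-D with planted labels.
makeBlobs <- function(nPer = 20, sep = 12, seed = 5) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(nPer * 2, sd = 0.5), nPer, 2), 2, centers[g, ], "+")))
  rownames(X) <- sprintf("pt%02d", seq_len(3 * nPer))
  list(X = X, labels = rep(1:3, each = nPer))
}

# A data matrix whose sample covariance has exactly the requested
# variance fractions: orthogonal centered columns (Helmert contrasts)
# rescaled to the target variances.
makeExactVarianceData <- function(fractions, n = 12) {
  H <- stats::contr.helmert(n)[, seq_along(fractions)]
  X <- sapply(seq_along(fractions), function(j) {
    col <- H[, j]
    col / stats::sd(col) * sqrt(fractions[j])
  })
  rownames(X) <- paste0("r", seq_len(n))
  X
}

# Adjusted Rand index between two partitions (independent of mclust so the
# oracle in tests can cross-check against it).
pairAgreement <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sumI * sumJ / total
  (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}

# Planted embedding vocabulary: `words` split into `G` groups.
plantedGrouping <- function(nWords, G) {
  words <- sprintf("word%02d", seq_len(nWords))
  g <- rep_len(seq_len(G), nWords)
  names(g) <- words
  g
}
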