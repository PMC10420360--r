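#' Cluster molecules in principal-component space
#'
#' Agglomerative clustering of molecules on Euclidean distance between their
#' PC scores. Ward linkage is the default because it pairs naturally with the
#' variance-based elbow criterion used to choose the cluster count; other
#' linkages are exposed.
#'
#' @param scores [FeatureTable-class] or matrix of PC scores (rownames =
#'   molecule ids).
#' @param nClusters number of clusters in [1, n molecules].
#' @param linkage hclust method (default "ward.D2").
#' @return named integer vector: molecule -> cluster index (clusters indexed
#'   in decreasing size).
#' @export
clusterMolecules <- function(scores, nClusters,
                             linkage = c("ward.D2", "average", "complete", "single")) {
  linkage <- match.arg(linkage)
  X <- .asFeatureMatrix(scores)
  if (!is.numeric(X) || anyNA(X)) stop("scores must be numeric without missing values")
  if (nClusters < 1 || nClusters > nrow(X))
    stop("nClusters must lie in [1, number of molecules]")
  raw <- stats::cutree(stats::hclust(stats::dist(X), method = linkage), k = nClusters)
  names(raw) <- rownames(X)
  clusterAssignments(.asGrouping(raw))
}

#' Within-cluster sum of squares curve
#'
#' W(k): total squared Euclidean distance of each point to its cluster
#' centroid, for each k in \code{kRange}, with clusters from
#' [clusterMolecules()].
#'
#' @param scores matrix or [FeatureTable-class].
#' @param kRange integer vector of cluster counts.
#' @param linkage passed to [clusterMolecules()].
#' @return named numeric vector W(k).
#' @export
wcssCurve <- function(scores, kRange, linkage = "ward.D2") {
  X <- .asFeatureMatrix(scores)
  w <- vapply(kRange, function(k) {
    a <- clusterMolecules(X, k, linkage = linkage)
    sum(vapply(unique(a), function(g) {
      pts <- X[a == g, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, 0))
  }, 0)
  names(w) <- kRange
  w
}

#' Select the cluster count by the elbow method
#'
#' Computes the within-cluster sum of squares W(k) over \code{kRange} and
#' returns the k at the sharpest bend: the maximizer of the second difference
#' W(k-1) - 2 W(k) + W(k+1) over the interior of the range (ties go to the
#' smallest k). This automates the visual elbow reading so the selection is
#' testable; the W(k) curve is attached for manual review.
#'
#' @param scores matrix or [FeatureTable-class].
#' @param kRange consecutive integer cluster counts (length >= 3).
#' @param linkage passed to [clusterMolecules()].
#' @return integer k, with attribute \code{"wcss"} holding the curve.
#' @export
elbowSelect <- function(scores, kRange, linkage = "ward.D2") {
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) < 3) stop("kRange must contain at least 3 cluster counts")
  w <- wcssCurve(scores, kRange, linkage = linkage)
  if (max(w) - min(w) == 0)      # flat curve (e.g. identical points): no elbow
    return(structure(kRange[1], wcss = w))
  inner <- seq(2, length(kRange) - 1)
  curvature <- w[inner - 1] - 2 * w[inner] + w[inner + 1]
  best <- kRange[inner][which.max(curvature)]   # which.max takes the first tie
  structure(as.integer(best), wcss = w)
}

#' Per-cluster composition of the top odor descriptors
#'
#' For the \code{topN} most frequent descriptors (by positive count, ties
#' broken lexicographically), computes the percentage of each descriptor's
#' positive molecules falling in each cluster: 100 x (positives inside the
#' cluster) / (total positives). Percentages for a descriptor sum to 100
#' across clusters. This is the radar-chart table of the cluster-composition
#' analysis.
#'
#' @param assignments named integer vector from [clusterMolecules()].
#' @param labels a [DescriptorMatrix-class] covering the same molecules.
#' @param topN number of descriptors to report (default 7).
#' @return A [CompositionResult-class].
#' @export
descriptorPercentages <- function(assignments, labels, topN = 7L) {
  Y <- .asLabelMatrix(labels)
  if (topN > ncol(Y)) stop("topN exceeds the vocabulary size")
  if (!is.null(names(assignments)) && !is.null(rownames(Y))) {
    if (!setequal(names(assignments), rownames(Y)))
      stop("assignments and labels cover different molecules")
    Y <- Y[names(assignments), , drop = FALSE]
  } else if (length(assignments) != nrow(Y)) {
    stop("assignments and labels cover different molecules")
  }
  counts <- colSums(Y)
  ord <- order(-counts, colnames(Y))
  top <- colnames(Y)[ord][seq_len(topN)]
  zero <- top[counts[top] == 0]
  if (length(zero)) {
    message("excluding zero-positive descriptor(s): ", paste(zero, collapse = ", "))
    top <- setdiff(top, zero)
  }
  clusters <- sort(unique(assignments))
  pct <- matrix(0, length(top), length(clusters),
    dimnames = list(top, as.character(clusters)))
  for (d in top) {
    inCluster <- vapply(clusters, function(g)
      sum(Y[assignments == g, d]), 0L)
    pct[d, ] <- 100 * inCluster / counts[[d]]
  }
  totals <- as.integer(counts[top])
  names(totals) <- top
  a <- as.integer(assignments)
  names(a) <- names(assignments)
  new("CompositionResult", assignments = a, percentages = pct,
    positiveTotals = totals, wcss = numeric(0))
}

#' Full composition analysis of a featurization
#'
#' Convenience pipeline: preprocess the feature table ([preprocessFeatures()]),
#' choose the cluster count by [elbowSelect()] (unless given), cluster the
#' molecules in PC space, and compute [descriptorPercentages()].
#'
#' @param table a [FeatureTable-class].
#' @param labels a [DescriptorMatrix-class].
#' @param nClusters cluster count, or NULL to select by elbow over
#'   \code{kRange}.
#' @param kRange candidate cluster counts for the elbow.
#' @param topN descriptors to report.
#' @param cutoff PCA cumulative-variance cutoff.
#' @return A [CompositionResult-class] with the W(k) curve in its wcss slot.
#' @export
compositionAnalysis <- function(table, labels, nClusters = NULL,
                                kRange = 2:10, topN = 7L, cutoff = 0.95) {
  scores <- preprocessFeatures(table, cutoff = cutoff)$scores
  w <- numeric(0)
  if (is.null(nClusters)) {
    k <- elbowSelect(scores, kRange)
    w <- attr(k, "wcss")
    nClusters <- as.integer(k)
  }
  assignments <- clusterMolecules(scores, nClusters)
  res <- descriptorPercentages(assignments, labels, topN = topN)
  res@wcss <- w
  res
}
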