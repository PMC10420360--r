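#' Cosine similarity of two vectors
#'
#' u.v / (|u||v|); zero vectors are rejected.
#'
#' @param u,v equal-length numeric vectors.
#' @return similarity in [-1, 1].
#' @examples
#' cosineSimilarity(c(1, 1), c(1, 0))   # sqrt(2)/2
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Embed the descriptor vocabulary
#'
#' Looks up each odor descriptor in a word-embedding table. Multi-word or
#' hyphenated descriptors are embedded as the mean of their token vectors;
#' a descriptor with no embeddable token raises an error naming it.
#'
#' @param vocab character vector of descriptors.
#' @param embedding matrix with words as rownames (see [readEmbeddingTable()]).
#' @return matrix of descriptor vectors (rownames = vocab).
#' @export
embedDescriptors <- function(vocab, embedding) {
  out <- t(vapply(vocab, function(word) {
    tokens <- strsplit(word, "[ -]+")[[1]]
    hits <- tokens[tokens %in% rownames(embedding)]
    if (!length(hits))
      stop("descriptor not in embedding vocabulary: ", word)
    colMeans(embedding[hits, , drop = FALSE])
  }, numeric(ncol(embedding))))
  rownames(out) <- vocab
  out
}

#' Pairwise cosine-similarity matrix over the vocabulary
#'
#' @param vectors matrix of descriptor vectors (rownames = descriptors).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
similarityMatrix <- function(vectors) {
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero vector in the embedding")
  unit <- vectors / norms
  s <- tcrossprod(unit)
  s <- (s + t(s)) / 2          # enforce exact symmetry
  diag(s) <- 1
  s
}

#' Cluster odor descriptors from a similarity matrix
#'
#' Agglomerative clustering on distance d = 1 - similarity; the tree is cut
#' at \code{nClusters}. Average linkage is the default reading of
#' "hierarchical clustering on the cosine-similarity matrix"; alternatives
#' are exposed. Cluster indices are relabeled in decreasing member count so
#' cluster 1 is the largest group regardless of dendrogram order.
#'
#' @param sim symmetric similarity matrix with descriptor dimnames.
#' @param nClusters number of groups, in [1, vocabulary size].
#' @param linkage hclust method: "average" (default), "complete", "single",
#'   "ward.D2".
#' @return A [DescriptorGrouping-class].
#' @export
clusterDescriptors <- function(sim, nClusters,
                               linkage = c("average", "complete", "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (is.null(rownames(sim))) stop("similarity matrix must carry descriptor names")
  if (max(abs(sim - t(sim))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(abs(diag(sim) - 1) > 1e-8)) stop("similarity diagonal must be 1")
  n <- nrow(sim)
  if (nClusters < 1 || nClusters > n)
    stop("nClusters must lie in [1, vocabulary size]")
  raw <- stats::cutree(stats::hclust(stats::as.dist(1 - sim), method = linkage),
    k = nClusters)
  .asGrouping(raw)
}

# Relabel a raw cluster vector so indices decrease in member count
# (ties: smaller original index first).
.asGrouping <- function(raw) {
  sizes <- table(raw)
  newIndex <- integer(length(sizes))
  newIndex[order(-as.integer(sizes), as.integer(names(sizes)))] <- seq_along(sizes)
  assignment <- newIndex[match(raw, as.integer(names(sizes)))]
  storage.mode(assignment) <- "integer"
  names(assignment) <- names(raw)
  new("DescriptorGrouping", assignment = assignment,
    nClusters = length(sizes))
}

#' Build group-level targets from a descriptor grouping
#'
#' A molecule is positive for a group if it carries any member descriptor
#' (logical OR over the group's columns).
#'
#' @param labels a [DescriptorMatrix-class].
#' @param grouping a [DescriptorGrouping-class] covering the label vocabulary.
#' @return A [DescriptorMatrix-class] whose columns are \code{group1..groupK}.
#' @export
buildGroupTargets <- function(labels, grouping) {
  Y <- .asLabelMatrix(labels)
  a <- clusterAssignments(grouping)
  missing <- setdiff(colnames(Y), names(a))
  if (length(missing))
    stop("descriptor(s) missing from the grouping: ", paste(missing, collapse = ", "))
  k <- nClusters(grouping)
  G <- vapply(seq_len(k), function(g) {
    members <- names(a)[a == g]
    members <- intersect(members, colnames(Y))
    as.integer(rowSums(Y[, members, drop = FALSE]) > 0)
  }, integer(nrow(Y)))
  dimnames(G) <- list(rownames(Y), paste0("group", seq_len(k)))
  DescriptorMatrix(G)
}

#' Evaluate group predictors in ROC space
#'
#' Runs [evaluateRepeatedCV()] on group-level targets (binary SVM by default,
#' as groups are far less imbalanced than single descriptors) and summarizes
#' each group by its mean true-positive rate, false-positive rate and F1 over
#' the folds. Groups positive for every sample have no negatives and are
#' excluded with a message.
#'
#' @param features [FeatureTable-class] or matrix.
#' @param groupTargets [DescriptorMatrix-class] from [buildGroupTargets()].
#' @param modelKind "binary_svm" (default) or "ocsvm".
#' @param spec,k,repeats,seed as in [evaluateRepeatedCV()].
#' @return A [GroupEvaluation-class].
#' @export
evaluateGroups <- function(features, groupTargets, modelKind = "binary_svm",
                           spec = NULL, k = 10L, repeats = 3L, seed = 1L) {
  res <- evaluateRepeatedCV(features, groupTargets, modelKind = modelKind,
    spec = spec, k = k, repeats = repeats, seed = seed)
  cnt <- foldCounts(res)
  tprFold <- cnt[, , "tp"] / pmax(1L, cnt[, , "tp"] + cnt[, , "fn"])
  fprFold <- cnt[, , "fp"] / pmax(1L, cnt[, , "fp"] + cnt[, , "tn"])
  if (is.null(dim(tprFold))) {               # single group
    tprFold <- matrix(tprFold, 1); fprFold <- matrix(fprFold, 1)
  }
  rates <- data.frame(group = rownames(foldF1(res)),
    tpr = rowMeans(tprFold), fpr = rowMeans(fprFold),
    f1 = meanF1(res), row.names = NULL)
  new("GroupEvaluation", rates = rates, evaluation = res)
}
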