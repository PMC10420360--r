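#' Min-max normalize a feature table
#'
#' Rescales every column into [0, 1] by (x - min) / (max - min). Constant
#' columns map to 0. The fitted per-column ranges are returned so the same
#' transform can be applied to new data with [applyRanges()]; reapplying the
#' fitted ranges to the training table is a no-op.
#'
#' @param table a [FeatureTable-class] or numeric matrix.
#' @return list with \code{table} (normalized, same class as the input for
#'   FeatureTable) and \code{ranges} (list of min and max vectors).
#' @examples
#' minmaxNormalize(matrix(c(0, 5, 10), 3, 1))$table
#' @export
minmaxNormalize <- function(table) {
  X <- .asFeatureMatrix(table)
  if (!length(X)) stop("cannot normalize an empty table")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  ranges <- list(min = mins, max = maxs)
  out <- applyRanges(X, ranges)
  if (is(table, "FeatureTable")) out <- FeatureTable(out, provenance(table))
  list(table = out, ranges = ranges)
}

#' @rdname minmaxNormalize
#' @param x numeric matrix to transform with previously fitted ranges.
#' @param ranges the \code{ranges} element returned by [minmaxNormalize()].
#' @export
applyRanges <- function(x, ranges) {
  X <- .asFeatureMatrix(x)
  span <- ranges$max - ranges$min
  span[span == 0] <- 1     # constant columns map to 0
  sweep(sweep(X, 2, ranges$min, "-"), 2, span, "/")
}

#' PCA reduction at a cumulative-variance cutoff
#'
#' Centers the (already normalized) table on its column means and computes
#' principal components, retaining the smallest number of components whose
#' cumulative explained-variance ratio reaches \code{cutoff}. A cumulative
#' ratio exactly equal to the cutoff counts as reaching it. No unit-variance
#' scaling is applied: the study pipeline normalizes to [0, 1] only.
#'
#' @param table a [FeatureTable-class] or numeric matrix (>= 2 rows).
#' @param cutoff cumulative-variance fraction in (0, 1]; default 0.95.
#' @param ranges optional normalizer ranges to record in the reduction.
#' @return list with \code{scores}, a [FeatureTable-class] of centered
#'   component scores (provenance preserved), and \code{reduction}, a
#'   [PCAReduction-class].
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' fit <- pcaReduce(X, cutoff = 0.95)
#' nComponents(fit$reduction)
#' @export
pcaReduce <- function(table, cutoff = 0.95, ranges = list()) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  X <- .asFeatureMatrix(table)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- fit$sdev^2
  total <- sum(vars)
  if (total == 0) stop("table has zero variance; nothing to reduce")
  ratios <- vars / total
  cum <- cumsum(ratios)
  ncomp <- which(cum >= cutoff - 1e-12)[1]
  scores <- fit$x[, seq_len(ncomp), drop = FALSE]
  if (is.null(rownames(scores))) rownames(scores) <- rownames(X)
  reduction <- new("PCAReduction",
    nComponents = as.integer(ncomp), cutoff = cutoff,
    cumulativeVariance = cum[ncomp],
    loadings = fit$rotation[, seq_len(ncomp), drop = FALSE],
    ratios = ratios, center = fit$center, ranges = ranges)
  prov <- if (is(table, "FeatureTable")) provenance(table) else "synthetic"
  list(scores = FeatureTable(scores, provenance = prov), reduction = reduction)
}

#' Normalize then PCA-reduce in one step
#'
#' Convenience wrapper running [minmaxNormalize()] followed by [pcaReduce()],
#' the standard preprocessing applied to every featurization before modeling.
#'
#' @inheritParams pcaReduce
#' @return as [pcaReduce()].
#' @export
preprocessFeatures <- function(table, cutoff = 0.95) {
  norm <- minmaxNormalize(table)
  pcaReduce(norm$table, cutoff = cutoff, ranges = norm$ranges)
}
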