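#' F1 and recall from confusion counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn), F1 = 2PR/(P+R), with every
#' 0/0 defined as 0 — the standard convention for rare-positive evaluation,
#' which keeps per-descriptor means defined when a validation fold has no
#' predicted or no actual positives.
#'
#' @param tp,fp,fn non-negative confusion counts (vectorized).
#' @return list with numeric \code{f1} and \code{recall}.
#' @examples
#' f1AndRecall(1, 1, 1)   # both 0.5
#' @export
f1AndRecall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall))
  list(f1 = f1, recall = recall)
}

#' One-class SVM specification
#'
#' @param nu fraction in (0, 1]: upper bound on the training-outlier fraction
#'   and lower bound on the support-vector fraction.
#' @param kernel "rbf" or "linear".
#' @param gamma positive number, or "scale" for the heuristic
#'   1 / (nFeatures * var(X)).
#' @return list of class "smellbench_ocsvm_spec".
#' @export
ocsvmSpec <- function(nu = 0.1, kernel = c("rbf", "linear"), gamma = "scale") {
  kernel <- match.arg(kernel)
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  if (is.numeric(gamma) && gamma <= 0) stop("gamma must be positive")
  structure(list(nu = nu, kernel = kernel, gamma = gamma, modelKind = "ocsvm"),
    class = "smellbench_ocsvm_spec")
}

#' Binary SVM specification
#'
#' @param cost the C regularization parameter (> 0).
#' @inheritParams ocsvmSpec
#' @return list of class "smellbench_svm_spec".
#' @export
binarySvmSpec <- function(cost = 1, kernel = c("rbf", "linear"), gamma = "scale") {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  structure(list(cost = cost, kernel = kernel, gamma = gamma,
    modelKind = "binary_svm"), class = "smellbench_svm_spec")
}

#' Default hyperparameter grids
#'
#' The documented stand-in search space: nu in {0.01, 0.05, 0.1, 0.2, 0.3,
#' 0.5} crossed with RBF gamma in {scale, 0.01, 0.1, 1} for the one-class
#' model, and C in {0.1, 1, 10, 100} with the same gammas for the binary SVM.
#'
#' @param modelKind "ocsvm" or "binary_svm".
#' @return list of specs.
#' @export
defaultGrid <- function(modelKind = c("ocsvm", "binary_svm")) {
  modelKind <- match.arg(modelKind)
  gammas <- list("scale", 0.01, 0.1, 1)
  if (modelKind == "ocsvm") {
    specs <- expand.grid(nu = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
      g = seq_along(gammas))
    lapply(seq_len(nrow(specs)), function(i)
      ocsvmSpec(nu = specs$nu[i], gamma = gammas[[specs$g[i]]]))
  } else {
    specs <- expand.grid(cost = c(0.1, 1, 10, 100), g = seq_along(gammas))
    lapply(seq_len(nrow(specs)), function(i)
      binarySvmSpec(cost = specs$cost[i], gamma = gammas[[specs$g[i]]]))
  }
}

.resolveGamma <- function(gamma, X) {
  if (is.numeric(gamma)) return(gamma)
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

.e1071Kernel <- function(kernel) if (kernel == "rbf") "radial" else "linear"

#' OCSVMModel: a fitted one-class frontier
#'
#' Wraps the fitted solver state for a one-class SVM trained on the
#' majority class: the decision functional w.phi(x) - b (rho), the support
#' vectors, and the realized nu-property fractions on the training set.
#' Training points with negative decision score are the flagged outliers.
#'
#' @slot fit the underlying solver fit.
#' @slot spec the [ocsvmSpec()] used.
#' @slot nFeatures training dimension.
#' @slot trainOutlierFraction fraction of training rows flagged out-of-class.
#' @slot svFraction fraction of training rows used as support vectors.
#'
#' @aliases show,OCSVMModel-method
#' @export
setClass("OCSVMModel",
  representation(fit = "ANY", spec = "list", nFeatures = "integer",
    trainOutlierFraction = "numeric", svFraction = "numeric"))

setMethod("show", "OCSVMModel", function(object) {
  cat(sprintf(
    "OCSVMModel: nu = %g, %s kernel, %d features\n  training outliers %.3f (<= nu), support vectors %.3f (>= nu)\n",
    object@spec$nu, object@spec$kernel, object@nFeatures,
    object@trainOutlierFraction, object@svFraction))
})

#' Train a one-class SVM on the majority class
#'
#' Fits the one-class frontier that separates the training cloud from the
#' origin in feature space. Per the evaluation protocol the training rows are
#' the descriptor-absent (majority) samples only. The nu parameter upper
#' bounds the fraction of training rows flagged as outliers and lower bounds
#' the support-vector fraction.
#'
#' @param X numeric matrix of majority-class rows (>= 2).
#' @param spec an [ocsvmSpec()].
#' @return An [OCSVMModel-class].
#' @export
trainOneClass <- function(X, spec = ocsvmSpec()) {
  X <- .asFeatureMatrix(X)
  if (nrow(X) < 2) stop("one-class training needs at least 2 rows")
  fit <- e1071::svm(X, y = NULL, type = "one-classification",
    kernel = .e1071Kernel(spec$kernel), nu = spec$nu,
    gamma = .resolveGamma(spec$gamma, X), scale = FALSE)
  inClass <- as.logical(stats::predict(fit, X))
  new("OCSVMModel", fit = fit, spec = unclass(spec), nFeatures = ncol(X),
    trainOutlierFraction = mean(!inClass),
    svFraction = fit$tot.nSV / nrow(X))
}

#' Decision scores of a one-class model
#'
#' @param model an [OCSVMModel-class].
#' @param X rows to score; must match the training dimension.
#' @return numeric scores; negative = out-of-class.
#' @export
decisionScores <- function(model, X) {
  X <- .asFeatureMatrix(X)
  if (ncol(X) != model@nFeatures)
    stop(sprintf("dimension mismatch: model trained on %d features, data has %d",
      model@nFeatures, ncol(X)))
  as.numeric(attr(stats::predict(model@fit, X, decision.values = TRUE),
    "decision.values"))
}

#' Predict descriptor presence from a one-class model
#'
#' The model is trained on descriptor-absent rows, so a row scored
#' out-of-class (negative decision score) is predicted descriptor-PRESENT.
#'
#' @param model an [OCSVMModel-class].
#' @param X rows to classify.
#' @return integer vector of 0/1 predictions (1 = descriptor present).
#' @export
predictDescriptor <- function(model, X) {
  as.integer(decisionScores(model, X) < 0)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# cyclically over the k folds, so positives are spread as evenly as the
# counts allow. Returns an n x repeats matrix of fold ids.
stratifiedFolds <- function(y, k, repeats, seed) {
  n <- length(y)
  if (k > n) stop("k exceeds the number of rows")
  folds <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    folds[, r] <- withSubstream(seed, paste0("folds_rep", r), {
      f <- integer(n)
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  }
  folds
}

#' Evaluate per-descriptor predictors under repeated stratified CV
#'
#' For every descriptor independently: build stratified k-fold splits
#' (repeated), train the model on each training fold, predict the validation
#' fold, and record F1 and recall from the fold confusion counts. One-class
#' models are fit on the training fold's majority (descriptor-absent) rows
#' only; binary SVMs use both classes. Descriptors with no positives (or no
#' negatives) are excluded with a message. Stratification is used because
#' with a dozen positives among ~114 samples, unstratified 10-fold splits
#' frequently produce positive-free validation folds on which F1 is
#' meaningless.
#'
#' @param features [FeatureTable-class] or matrix of (preprocessed) features.
#' @param labels [DescriptorMatrix-class] or binary matrix, row-aligned with
#'   the features.
#' @param modelKind "ocsvm" or "binary_svm".
#' @param spec model spec; defaults to [ocsvmSpec()] / [binarySvmSpec()].
#' @param k folds (>= 2); @param repeats repetitions; @param seed integer seed.
#' @return An [EvaluationResult-class].
#' @export
evaluateRepeatedCV <- function(features, labels,
                               modelKind = c("ocsvm", "binary_svm"),
                               spec = NULL, k = 10L, repeats = 3L, seed = 1L) {
  modelKind <- match.arg(modelKind)
  if (is.null(spec))
    spec <- if (modelKind == "ocsvm") ocsvmSpec() else binarySvmSpec()
  X <- .asFeatureMatrix(features)
  Y <- .asLabelMatrix(labels)
  .checkAligned(X, Y)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(X)) stop("k exceeds the number of rows")
  pos <- colSums(Y)
  excluded <- colnames(Y)[pos == 0 | pos == nrow(Y)]
  if (length(excluded))
    message("excluding target(s) without both classes: ",
      paste(excluded, collapse = ", "))
  keep <- setdiff(colnames(Y), excluded)
  if (!length(keep)) stop("no evaluable targets remain")
  nFolds <- k * repeats
  foldNames <- paste0("fold", seq_len(nFolds))
  f1m <- matrix(NA_real_, length(keep), nFolds, dimnames = list(keep, foldNames))
  recm <- f1m
  counts <- array(0L, c(length(keep), nFolds, 4L),
    dimnames = list(keep, foldNames, c("tp", "fp", "fn", "tn")))
  for (d in seq_along(keep)) {
    y <- Y[, keep[d]]
    folds <- stratifiedFolds(y, k, repeats,
      substreamSeed(seed, paste0("cv_", keep[d])))
    col <- 0L
    for (r in seq_len(repeats)) {
      for (fold in seq_len(k)) {
        col <- col + 1L
        val <- folds[, r] == fold
        pred <- .fitPredictFold(X, y, val, modelKind, spec)
        tp <- sum(pred == 1L & y[val] == 1L)
        fp <- sum(pred == 1L & y[val] == 0L)
        fn <- sum(pred == 0L & y[val] == 1L)
        tn <- sum(pred == 0L & y[val] == 0L)
        m <- f1AndRecall(tp, fp, fn)
        f1m[d, col] <- m$f1
        recm[d, col] <- m$recall
        counts[d, col, ] <- c(tp, fp, fn, tn)
      }
    }
  }
  new("EvaluationResult", foldF1 = f1m, foldRecall = recm, counts = counts,
    plan = list(k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed), modelKind = modelKind, spec = unclass(spec)),
    excluded = excluded)
}

.fitPredictFold <- function(X, y, val, modelKind, spec) {
  Xtr <- X[!val, , drop = FALSE]
  ytr <- y[!val]
  Xva <- X[val, , drop = FALSE]
  if (modelKind == "ocsvm") {
    maj <- Xtr[ytr == 0L, , drop = FALSE]
    if (nrow(maj) < 2) return(rep(1L, nrow(Xva)))
    model <- trainOneClass(maj, spec)
    predictDescriptor(model, Xva)
  } else {
    if (length(unique(ytr)) < 2) return(rep(ytr[1], nrow(Xva)))
    fit <- e1071::svm(Xtr, factor(ytr, levels = c(0L, 1L)),
      type = "C-classification", kernel = .e1071Kernel(spec$kernel),
      cost = spec$cost, gamma = .resolveGamma(spec$gamma, Xtr), scale = FALSE)
    as.integer(as.character(stats::predict(fit, Xva)))
  }
}

#' Per-descriptor hyperparameter search
#'
#' Evaluates every grid point with [evaluateRepeatedCV()] and selects, per
#' descriptor, the spec maximizing mean validation F1. Ties are broken toward
#' the smaller nu (or cost), then the smaller resolved gamma.
#'
#' @param features,labels as in [evaluateRepeatedCV()].
#' @param grid non-empty list of [ocsvmSpec()] or [binarySvmSpec()] objects.
#' @param k,repeats,seed CV plan for the search.
#' @return named list: descriptor -> best spec, with the grid's mean-F1 table
#'   attached as attribute \code{"f1"} (descriptors x grid points).
#' @export
searchHyperparameters <- function(features, labels, grid, k = 5L,
                                  repeats = 1L, seed = 1L) {
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  kinds <- unique(vapply(grid, `[[`, "", "modelKind"))
  if (length(kinds) != 1) stop("grid must contain one model kind")
  X <- .asFeatureMatrix(features)
  f1 <- sapply(grid, function(spec) {
    res <- suppressMessages(evaluateRepeatedCV(features, labels,
      modelKind = kinds, spec = spec, k = k, repeats = repeats, seed = seed))
    meanF1(res)
  })
  if (is.null(dim(f1))) f1 <- matrix(f1, nrow = 1)
  primary <- vapply(grid, function(s)
    if (kinds == "ocsvm") s$nu else s$cost, 0)
  gammas <- vapply(grid, function(s) .resolveGamma(s$gamma, X), 0)
  best <- apply(f1, 1, function(row) {
    o <- order(-row, primary, gammas)
    o[1]
  })
  out <- lapply(best, function(i) grid[[i]])
  names(out) <- rownames(f1)
  attr(out, "f1") <- f1
  out
}

#' Paired t-test between two feature-set evaluations
#'
#' Pairs the per-descriptor mean F1 of two evaluations over the same targets
#' and tests the mean difference with a paired two-sided Student t-test
#' (t = mean(d) / (sd(d)/sqrt(n)), n-1 df). Zero-variance differences are
#' flagged degenerate rather than producing NaN; identical results report the
#' exactly-equal flag.
#'
#' @param resultA,resultB [EvaluationResult-class] objects with identical
#'   target sets in identical order (or plain named numeric vectors of
#'   per-target mean F1).
#' @return A [ComparisonResult-class].
#' @export
compareFeatureSets <- function(resultA, resultB) {
  a <- if (is(resultA, "EvaluationResult")) meanF1(resultA) else resultA
  b <- if (is(resultB, "EvaluationResult")) meanF1(resultB) else resultB
  if (length(a) != length(b))
    stop("results cover different numbers of targets")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("results must cover the same targets in the same order")
  d <- a - b
  n <- length(d)
  if (n < 2) stop("paired comparison needs at least 2 targets")
  s <- stats::sd(d)
  if (s == 0) {
    return(new("ComparisonResult", statistic = NA_real_,
      pValue = if (mean(d) == 0) NA_real_ else 0,
      nPairs = as.integer(n), meanDifference = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  new("ComparisonResult", statistic = t, pValue = p, nPairs = as.integer(n),
    meanDifference = mean(d), degenerate = FALSE)
}

#' Permutation-null distribution of the overall mean F1
#'
#' Destroys the feature-label association by permuting the label rows and
#' re-running the full evaluation; the overall mean F1 across descriptors of
#' each permutation forms the null distribution against which an observed
#' evaluation is judged.
#'
#' @param features,labels,modelKind,spec,k,repeats as in [evaluateRepeatedCV()].
#' @param nPermutations number of label permutations.
#' @param seed integer seed (permutation r uses substream "perm_r").
#' @return descriptors x permutations matrix of per-descriptor mean F1 under
#'   the null; \code{colMeans()} of it is the null distribution of the
#'   overall mean F1.
#' @export
permutationNullF1 <- function(features, labels, modelKind = "ocsvm",
                              spec = NULL, k = 10L, repeats = 3L,
                              nPermutations = 8L, seed = 1L) {
  Y <- .asLabelMatrix(labels)
  cols <- lapply(seq_len(nPermutations), function(r) {
    perm <- withSubstream(seed, paste0("perm_", r), sample(nrow(Y)))
    Yp <- Y[perm, , drop = FALSE]
    rownames(Yp) <- rownames(Y)
    res <- suppressMessages(evaluateRepeatedCV(features, Yp,
      modelKind = modelKind, spec = spec, k = k, repeats = repeats,
      seed = substreamSeed(seed, paste0("perm_eval_", r))))
    meanF1(res)
  })
  do.call(cbind, cols)
}
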