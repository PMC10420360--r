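#' Run configuration
#'
#' A single declarative configuration object for a benchmark run. Defaults
#' follow the study protocol: keep 95% of total variance at PCA reduction and
#' evaluate with 10-fold cross-validation repeated 3 times.
#'
#' @param varianceCutoff cumulative explained-variance fraction in (0, 1].
#' @param kFolds number of CV folds (>= 2).
#' @param nRepeats number of CV repetitions (>= 1).
#' @param modelKind "ocsvm" or "binary_svm".
#' @param nLabelClusters number of odor-descriptor groups.
#' @param randomSeed integer seed expanded into per-operation substreams.
#' @return A list of class "smellbench_config".
#' @examples
#' cfg <- runConfig(randomSeed = 7)
#' cfg$kFolds
#' @export
runConfig <- function(varianceCutoff = 0.95, kFolds = 10L, nRepeats = 3L,
                      modelKind = c("ocsvm", "binary_svm"),
                      nLabelClusters = 6L, randomSeed = 1L) {
  modelKind <- match.arg(modelKind)
  stopifnot(
    varianceCutoff > 0, varianceCutoff <= 1,
    kFolds >= 2, nRepeats >= 1, nLabelClusters >= 1
  )
  structure(list(
    varianceCutoff = varianceCutoff, kFolds = as.integer(kFolds),
    nRepeats = as.integer(nRepeats), modelKind = modelKind,
    nLabelClusters = as.integer(nLabelClusters),
    randomSeed = as.integer(randomSeed)
  ), class = "smellbench_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected so that typos in config files surface early.
#' Values given in `overrides` (e.g. from CLI flags) take precedence over the
#' file.
#'
#' @param path path to a JSON file whose keys match [runConfig()] arguments.
#' @param overrides named list of values overriding the file.
#' @return A "smellbench_config" list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

# One global seed expands into per-operation substreams so that adding or
# reordering a pipeline stage never perturbs the draws of another stage.
# The stream label is hashed into [0, 2^20); the combination stays < 2^31.
substreamSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 1048576
  as.integer((abs(as.double(seed)) * 1009 + h) %% 2147483647)
}

withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, stream))
  force(expr)
}

# shared coercions -----------------------------------------------------------

.asFeatureMatrix <- function(x) {
  if (is(x, "FeatureTable")) featureMatrix(x) else as.matrix(x)
}

.asLabelMatrix <- function(x) {
  if (is(x, "DescriptorMatrix")) labelMatrix(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "integer"
    m
  }
}

.checkAligned <- function(X, Y) {
  if (nrow(X) != nrow(Y))
    stop("features and labels must have the same number of rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("features and labels are not aligned: rownames differ")
  invisible(TRUE)
}
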