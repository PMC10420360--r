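#' SensorTrace: one QCM sensor measurement
#'
#' A single e-nose measurement of one sample: a channels x timepoints matrix of
#' resonance-frequency readings (Hz), one row per receptor membrane, together
#' with the sampling interval and the index of the first reading taken with the
#' sample shutter open. The instrument emulated here carries 35 membranes and
#' records 300 readings at 0.1 s, but both dimensions are free.
#'
#' @slot readings numeric matrix, channels x timepoints.
#' @slot samplingInterval sampling interval in seconds (default 0.1).
#' @slot shutterOpenIndex 1-based index of the first exposed reading; readings
#'   strictly before it form the pre-exposure baseline window.
#'
#' @aliases channelCount,SensorTrace-method samplingInterval,SensorTrace-method
#'   shutterOpenIndex,SensorTrace-method traceMatrix,SensorTrace-method
#'   show,SensorTrace-method
#' @export
setClass("SensorTrace",
  representation(
    readings = "matrix",
    samplingInterval = "numeric",
    shutterOpenIndex = "integer"
  )
)

setValidity("SensorTrace", function(object) {
  m <- object@readings
  if (!is.numeric(m)) return("readings must be a numeric matrix")
  if (ncol(m) < 2L) return("a trace needs at least 2 timepoints")
  if (anyNA(m) || any(!is.finite(m))) return("readings must be finite")
  if (length(object@samplingInterval) != 1L || object@samplingInterval <= 0)
    return("samplingInterval must be a single positive number")
  i <- object@shutterOpenIndex
  if (length(i) != 1L || is.na(i) || i < 2L || i > ncol(m))
    return("shutterOpenIndex must lie in [2, timepoints] so that a pre-exposure window exists")
  TRUE
})

#' Construct a SensorTrace
#'
#' @param readings channels x timepoints numeric matrix of frequency readings (Hz).
#' @param samplingInterval seconds between readings.
#' @param shutterOpenIndex index of the first reading with the shutter open.
#' @return A [SensorTrace-class] object.
#' @examples
#' tr <- SensorTrace(matrix(1000, 2, 10), shutterOpenIndex = 4)
#' channelCount(tr)
#' @export
SensorTrace <- function(readings, samplingInterval = 0.1, shutterOpenIndex) {
  if (missing(shutterOpenIndex))
    stop("shutterOpenIndex is required: the pre-exposure window is not a constant of the format")
  new("SensorTrace",
    readings = as.matrix(readings),
    samplingInterval = as.numeric(samplingInterval),
    shutterOpenIndex = as.integer(shutterOpenIndex))
}

#' @export
setMethod("channelCount", "SensorTrace", function(x) nrow(x@readings))
#' @export
setMethod("samplingInterval", "SensorTrace", function(x) x@samplingInterval)
#' @export
setMethod("shutterOpenIndex", "SensorTrace", function(x) x@shutterOpenIndex)
#' @export
setMethod("traceMatrix", "SensorTrace", function(x) x@readings)

setMethod("show", "SensorTrace", function(object) {
  cat(sprintf("SensorTrace: %d channels x %d readings (dt = %g s, shutter opens at reading %d)\n",
    nrow(object@readings), ncol(object@readings),
    object@samplingInterval, object@shutterOpenIndex))
})

#' FeatureTable: one named featurization of a molecule cohort
#'
#' A molecules x features numeric matrix with a provenance tag recording which
#' featurization produced it: \code{enose} (QCM smell vectors), \code{bfp}
#' (bit Morgan fingerprints), \code{cfp} (count Morgan fingerprints),
#' \code{descriptors} (numeric molecular descriptors), \code{spectrum}
#' (mass-spectrum intensities), or \code{synthetic}. Row names are molecule ids
#' and define the alignment contract across modalities.
#'
#' @slot values numeric matrix with molecule ids as row names.
#' @slot provenance length-1 character provenance tag.
#'
#' @aliases featureMatrix,FeatureTable-method provenance,FeatureTable-method
#'   show,FeatureTable-method dim,FeatureTable-method
#' @export
setClass("FeatureTable",
  representation(values = "matrix", provenance = "character"))

.provenances <- c("enose", "bfp", "cfp", "descriptors", "spectrum", "synthetic")

setValidity("FeatureTable", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (is.null(rownames(object@values))) return("values must carry molecule ids as rownames")
  if (anyDuplicated(rownames(object@values))) return("molecule ids must be unique")
  if (length(object@provenance) != 1L || !object@provenance %in% .provenances)
    return(sprintf("provenance must be one of: %s", paste(.provenances, collapse = ", ")))
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values molecules x features numeric matrix (rownames = molecule ids).
#' @param provenance one of \code{"enose"}, \code{"bfp"}, \code{"cfp"},
#'   \code{"descriptors"}, \code{"spectrum"}, \code{"synthetic"}.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(values, provenance = "synthetic") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("r", seq_len(nrow(values)))
  new("FeatureTable", values = values, provenance = provenance)
}

#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@values)
#' @export
setMethod("provenance", "FeatureTable", function(x) x@provenance)
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s]: %d molecules x %d features\n",
    object@provenance, nrow(object@values), ncol(object@values)))
})

#' DescriptorMatrix: binary multilabel annotations
#'
#' Molecules x odor-descriptors binary matrix; column names are the descriptor
#' vocabulary (lower-case), row names the molecule ids.
#'
#' @slot labels integer matrix of 0/1 values.
#'
#' @aliases labelMatrix,DescriptorMatrix-method vocabulary,DescriptorMatrix-method
#'   show,DescriptorMatrix-method dim,DescriptorMatrix-method
#' @export
setClass("DescriptorMatrix", representation(labels = "matrix"))

setValidity("DescriptorMatrix", function(object) {
  m <- object@labels
  if (!all(m %in% c(0L, 1L))) return("labels must be binary 0/1")
  if (is.null(colnames(m)) || any(!nzchar(colnames(m))))
    return("descriptor names must be non-empty column names")
  if (anyDuplicated(colnames(m))) return("descriptor vocabulary must be unique")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("molecule ids must be unique rownames")
  TRUE
})

#' Construct a DescriptorMatrix
#'
#' @param labels molecules x descriptors binary matrix; colnames are the
#'   descriptor vocabulary, rownames the molecule ids.
#' @return A [DescriptorMatrix-class] object.
#' @export
DescriptorMatrix <- function(labels) {
  m <- as.matrix(labels)
  storage.mode(m) <- "integer"
  new("DescriptorMatrix", labels = m)
}

#' @export
setMethod("labelMatrix", "DescriptorMatrix", function(x) x@labels)
#' @export
setMethod("vocabulary", "DescriptorMatrix", function(x) colnames(x@labels))
#' @export
setMethod("dim", "DescriptorMatrix", function(x) dim(x@labels))

setMethod("show", "DescriptorMatrix", function(object) {
  pos <- colSums(object@labels)
  cat(sprintf("DescriptorMatrix: %d molecules x %d descriptors (positives: max %d, median %g)\n",
    nrow(object@labels), ncol(object@labels), max(pos), stats::median(pos)))
})

#' PCAReduction: a fitted variance-threshold PCA
#'
#' Records the principal-component reduction of a normalized feature table:
#' the minimal number of components whose cumulative explained-variance ratio
#' reaches the cutoff, the loadings, the per-component ratios, the column
#' centering used, and the min-max ranges fitted by the normalizer (so the
#' transform can be reapplied to new data).
#'
#' @slot nComponents minimal number of retained components.
#' @slot cutoff the cumulative-variance cutoff used.
#' @slot cumulativeVariance cumulative ratio actually attained.
#' @slot loadings columns = retained component loadings.
#' @slot ratios all explained-variance ratios, non-increasing.
#' @slot center column means of the normalized table.
#' @slot ranges list(min=, max=) fitted by the normalizer (may be empty).
#'
#' @aliases nComponents,PCAReduction-method varianceRatios,PCAReduction-method
#'   show,PCAReduction-method
#' @export
setClass("PCAReduction",
  representation(
    nComponents = "integer", cutoff = "numeric", cumulativeVariance = "numeric",
    loadings = "matrix", ratios = "numeric", center = "numeric", ranges = "list"))

setValidity("PCAReduction", function(object) {
  r <- object@ratios
  if (any(diff(r) > 1e-8)) return("explained-variance ratios must be non-increasing")
  if (sum(r) > 1 + 1e-8) return("explained-variance ratios must sum to at most 1")
  if (object@cumulativeVariance < object@cutoff - 1e-12)
    return("cumulative variance of retained components must reach the cutoff")
  TRUE
})

#' @export
setMethod("nComponents", "PCAReduction", function(x) x@nComponents)
#' @export
setMethod("varianceRatios", "PCAReduction", function(x) x@ratios)

setMethod("show", "PCAReduction", function(object) {
  cat(sprintf("PCAReduction: %d components keep %.4f of variance (cutoff %.2f)\n",
    object@nComponents, object@cumulativeVariance, object@cutoff))
})

#' EvaluationResult: repeated-CV metrics per target label
#'
#' Fold-level F1 and recall for every evaluated target (odor descriptor or
#' descriptor group) under repeated stratified k-fold cross-validation, with
#' the confusion counts retained per fold and the CV plan (k, repeats, seed,
#' model kind) recorded for reproducibility.
#'
#' @slot foldF1 targets x (k*repeats) matrix of fold F1 values.
#' @slot foldRecall targets x (k*repeats) matrix of fold recall values.
#' @slot counts targets x folds x 4 array of tp, fp, fn, tn.
#' @slot plan list with k, repeats, seed, modelKind and the model spec.
#' @slot excluded character: targets dropped (no positives / no negatives).
#'
#' @aliases meanF1,EvaluationResult-method meanRecall,EvaluationResult-method
#'   foldF1,EvaluationResult-method foldRecall,EvaluationResult-method
#'   foldCounts,EvaluationResult-method cvPlan,EvaluationResult-method
#'   show,EvaluationResult-method
#' @export
setClass("EvaluationResult",
  representation(foldF1 = "matrix", foldRecall = "matrix",
    counts = "array", plan = "list", excluded = "character"))

setValidity("EvaluationResult", function(object) {
  f <- object@foldF1
  if (any(f < -1e-12 | f > 1 + 1e-12, na.rm = TRUE)) return("F1 must lie in [0,1]")
  r <- object@foldRecall
  if (any(r < -1e-12 | r > 1 + 1e-12, na.rm = TRUE)) return("recall must lie in [0,1]")
  if (!identical(dim(f), dim(r))) return("foldF1 and foldRecall must be conformable")
  plan <- object@plan
  if (ncol(f) != plan$k * plan$repeats)
    return("number of fold values must equal k * repeats")
  TRUE
})

#' @export
setMethod("meanF1", "EvaluationResult", function(x) rowMeans(x@foldF1))
#' @export
setMethod("meanRecall", "EvaluationResult", function(x) rowMeans(x@foldRecall))
#' @export
setMethod("foldF1", "EvaluationResult", function(x) x@foldF1)
#' @export
setMethod("foldRecall", "EvaluationResult", function(x) x@foldRecall)
#' @export
setMethod("foldCounts", "EvaluationResult", function(x) x@counts)
#' @export
setMethod("cvPlan", "EvaluationResult", function(x) x@plan)

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult [%s]: %d targets, %d-fold CV x %d repeats\n  overall mean F1 = %.3f, mean recall = %.3f\n",
    object@plan$modelKind, nrow(object@foldF1), object@plan$k, object@plan$repeats,
    mean(rowMeans(object@foldF1)), mean(rowMeans(object@foldRecall))))
  if (length(object@excluded))
    cat("  excluded targets:", paste(object@excluded, collapse = ", "), "\n")
})

#' ComparisonResult: paired t-test between two feature sets
#'
#' Paired comparison of per-target mean F1 between two evaluations sharing the
#' same target set. When every paired difference is zero the comparison is
#' flagged degenerate instead of producing NaN.
#'
#' @slot statistic paired t statistic.
#' @slot pValue two-sided p-value from Student t with nPairs-1 df.
#' @slot nPairs number of paired targets.
#' @slot meanDifference mean of the paired differences (a - b).
#' @slot degenerate TRUE when the differences have zero variance.
#'
#' @aliases show,ComparisonResult-method
#' @export
setClass("ComparisonResult",
  representation(statistic = "numeric", pValue = "numeric", nPairs = "integer",
    meanDifference = "numeric", degenerate = "logical"))

setMethod("show", "ComparisonResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("ComparisonResult: exactly equal on all %d pairs (degenerate)\n", object@nPairs))
  } else {
    cat(sprintf("ComparisonResult: t = %.4f, p = %.4g (n = %d pairs, mean diff = %.4f)\n",
      object@statistic, object@pValue, object@nPairs, object@meanDifference))
  }
})

#' DescriptorGrouping: a partition of the descriptor vocabulary
#'
#' Maps every odor descriptor to a cluster index in 1..nClusters. Cluster
#' indices are assigned in decreasing order of member count so that cluster 1
#' is always the largest group.
#'
#' @slot assignment named integer vector, descriptor -> cluster index.
#' @slot nClusters number of clusters; all clusters are non-empty.
#'
#' @aliases clusterAssignments,DescriptorGrouping-method
#'   nClusters,DescriptorGrouping-method show,DescriptorGrouping-method
#' @export
setClass("DescriptorGrouping",
  representation(assignment = "integer", nClusters = "integer"))

setValidity("DescriptorGrouping", function(object) {
  a <- object@assignment
  if (is.null(names(a)) || any(!nzchar(names(a)))) return("assignment must be named by descriptor")
  if (anyDuplicated(names(a))) return("each descriptor is assigned exactly once")
  k <- object@nClusters
  if (!setequal(unique(a), seq_len(k))) return("every cluster in 1..nClusters must be non-empty")
  TRUE
})

#' @export
setMethod("clusterAssignments", "DescriptorGrouping", function(x) x@assignment)
#' @export
setMethod("nClusters", "DescriptorGrouping", function(x) x@nClusters)

setMethod("show", "DescriptorGrouping", function(object) {
  sizes <- table(object@assignment)
  cat(sprintf("DescriptorGrouping: %d descriptors in %d clusters (sizes %s)\n",
    length(object@assignment), object@nClusters, paste(sizes, collapse = ", ")))
})

#' GroupEvaluation: ROC-space metrics for descriptor groups
#'
#' Per-group true-positive rate, false-positive rate and F1 over repeated CV,
#' with the underlying fold-level [EvaluationResult-class] retained.
#'
#' @slot rates data.frame with columns group, tpr, fpr, f1.
#' @slot evaluation the fold-level evaluation the rates are derived from.
#'
#' @aliases show,GroupEvaluation-method
#' @export
setClass("GroupEvaluation",
  representation(rates = "data.frame", evaluation = "EvaluationResult"))

setValidity("GroupEvaluation", function(object) {
  r <- object@rates
  if (!all(c("group", "tpr", "fpr", "f1") %in% names(r))) return("rates needs group/tpr/fpr/f1")
  ok <- function(v) all(v >= -1e-12 & v <= 1 + 1e-12, na.rm = TRUE)
  if (!ok(r$tpr) || !ok(r$fpr) || !ok(r$f1)) return("rates must lie in [0,1]")
  TRUE
})

setMethod("show", "GroupEvaluation", function(object) {
  cat(sprintf("GroupEvaluation: %d groups\n", nrow(object@rates)))
  print(object@rates, row.names = FALSE)
})

#' CompositionResult: per-cluster composition of top descriptors
#'
#' For each of the top-N odor descriptors (by positive count), the percentage
#' of its positive molecules falling in each molecule cluster. Percentages for
#' one descriptor sum to 100 across clusters.
#'
#' @slot assignments named integer vector, molecule -> cluster.
#' @slot percentages descriptors x clusters matrix of percentages.
#' @slot positiveTotals named integer: total positives per listed descriptor.
#' @slot wcss optional named numeric: within-cluster sum of squares per k.
#'
#' @aliases clusterAssignments,CompositionResult-method
#'   show,CompositionResult-method
#' @export
setClass("CompositionResult",
  representation(assignments = "integer", percentages = "matrix",
    positiveTotals = "integer", wcss = "numeric"))

setValidity("CompositionResult", function(object) {
  s <- rowSums(object@percentages)
  if (any(abs(s - 100) > 1e-9)) return("percentages must sum to 100 per descriptor")
  if (any(object@percentages < -1e-12)) return("percentages must be non-negative")
  TRUE
})

#' @export
setMethod("clusterAssignments", "CompositionResult", function(x) x@assignments)

setMethod("show", "CompositionResult", function(object) {
  cat(sprintf("CompositionResult: %d descriptors across %d molecule clusters\n",
    nrow(object@percentages), ncol(object@percentages)))
  print(round(object@percentages, 2))
})

#' DatasetBundle: a cohort with its measurements
#'
#' Bundles a molecule table (id, CAS, SMILES, odor descriptors) with whatever
#' measurements exist for the cohort: raw sensor-trace replicates, an averaged
#' smell-vector table, and electron-ionization mass spectra. Every trace or
#' spectrum key must be a known molecule id.
#'
#' @slot molecules data.frame with columns id, cas, smiles and a list column
#'   descriptors (character vectors, lower-case, de-duplicated).
#' @slot traces named list: molecule id -> list of [SensorTrace-class] replicates.
#' @slot smellVectors a [FeatureTable-class] (provenance enose) or NULL.
#' @slot spectra named list: molecule id -> data.frame(mz, intensity).
#'
#' @aliases show,DatasetBundle-method
#' @export
setClass("DatasetBundle",
  representation(molecules = "data.frame", traces = "list",
    smellVectors = "ANY", spectra = "list"))

setValidity("DatasetBundle", function(object) {
  mol <- object@molecules
  if (!all(c("id", "descriptors") %in% names(mol)))
    return("molecules needs at least id and descriptors columns")
  if (anyDuplicated(mol$id)) return("molecule ids must be unique")
  desc <- unlist(mol$descriptors, use.names = FALSE)
  if (length(desc)) {
    if (any(!nzchar(desc))) return("descriptor strings must be non-empty")
    if (any(desc != tolower(desc))) return("descriptors must be lower-cased on ingest")
  }
  for (slotname in c("traces", "spectra")) {
    keys <- names(slot(object, slotname))
    if (length(keys) && !all(keys %in% mol$id))
      return(sprintf("every %s key must be a known molecule id", slotname))
  }
  if (!is.null(object@smellVectors) && !is(object@smellVectors, "FeatureTable"))
    return("smellVectors must be a FeatureTable or NULL")
  TRUE
})

#' Construct a DatasetBundle
#'
#' @param molecules molecule data.frame (see [DatasetBundle-class]).
#' @param traces named list of SensorTrace replicate lists.
#' @param smellVectors optional enose [FeatureTable-class].
#' @param spectra named list of data.frame(mz, intensity).
#' @return A [DatasetBundle-class].
#' @export
DatasetBundle <- function(molecules, traces = list(), smellVectors = NULL,
                          spectra = list()) {
  new("DatasetBundle", molecules = molecules, traces = traces,
    smellVectors = smellVectors, spectra = spectra)
}

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf("DatasetBundle: %d molecules, %d with traces, %d with spectra\n",
    nrow(object@molecules), length(object@traces), length(object@spectra)))
})
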