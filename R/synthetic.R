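#' Ground truth for synthetic sensor traces
#'
#' Describes the waveform planted in generated QCM traces. Before the shutter
#' opens a channel sits at its base frequency plus Gaussian noise; after
#' opening, adsorption pulls the frequency down toward base - magnitude with
#' an exponential approach (time constant \code{riseTau}). The rise is
#' rescaled so the shift attains exactly the planted magnitude five time
#' constants after onset, after which it holds, or decays exponentially at
#' \code{decayRate} if the headspace washes out. The planted magnitudes are
#' therefore exact oracles for the base-to-peak extraction.
#'
#' @param baseFrequency per-channel base frequency (Hz).
#' @param shiftMagnitude per-channel peak shift magnitude (Hz, >= 0); may also
#'   be a samples x channels matrix to give each sample its own response.
#' @param onsetIndex reading index at which the shutter opens.
#' @param riseTau rise time constant (s).
#' @param decayRate post-peak exponential decay rate (1/s, 0 = plateau).
#' @param noiseSd sd of the additive Gaussian reading noise (Hz, >= 0).
#' @return list of class "smellbench_trace_truth".
#' @examples
#' truth <- traceGroundTruth(rep(30000, 35), runif(35, 20, 120), onsetIndex = 100)
#' @export
traceGroundTruth <- function(baseFrequency, shiftMagnitude, onsetIndex,
                             riseTau = 2, decayRate = 0, noiseSd = 0) {
  if (noiseSd < 0) stop("noise sd must be non-negative")
  if (any(shiftMagnitude < 0)) stop("shift magnitudes must be non-negative")
  if (riseTau <= 0) stop("riseTau must be positive")
  if (decayRate < 0) stop("decayRate must be non-negative")
  nch <- length(baseFrequency)
  if (is.matrix(shiftMagnitude)) {
    if (ncol(shiftMagnitude) != nch)
      stop("shiftMagnitude matrix must have one column per channel")
  } else if (length(shiftMagnitude) != nch) {
    stop("baseFrequency and shiftMagnitude must have the same length")
  }
  structure(list(baseFrequency = baseFrequency, shiftMagnitude = shiftMagnitude,
    onsetIndex = as.integer(onsetIndex), riseTau = riseTau,
    decayRate = decayRate, noiseSd = noiseSd),
    class = "smellbench_trace_truth")
}

#' Generate synthetic QCM sensor traces
#'
#' Emulates the e-nose measurement protocol: for each of \code{nSamples}
#' molecules, \code{nReplicates} independent 35 x 300-style traces with the
#' waveform described by the [traceGroundTruth()]. With \code{noiseSd = 0} the
#' extracted base-to-peak deltas equal the planted magnitudes exactly.
#'
#' @param nSamples number of molecules.
#' @param truth a [traceGroundTruth()].
#' @param nReplicates replicate measurements per molecule (study protocol: 3).
#' @param seed integer seed (expanded into a substream).
#' @param nTimepoints readings per trace (default 300).
#' @param samplingInterval seconds between readings (default 0.1).
#' @param ids molecule ids; default mol001, mol002, ...
#' @return named list: id -> list of [SensorTrace-class] replicates.
#' @export
generateTraces <- function(nSamples, truth, nReplicates = 3L, seed = 1L,
                           nTimepoints = 300L, samplingInterval = 0.1,
                           ids = sprintf("mol%03d", seq_len(nSamples))) {
  stopifnot(is(truth, "smellbench_trace_truth"), nReplicates >= 1)
  if (truth$onsetIndex < 2L || truth$onsetIndex > nTimepoints)
    stop("onset index must lie within the trace")
  nch <- length(truth$baseFrequency)
  mags <- truth$shiftMagnitude
  if (!is.matrix(mags)) mags <- matrix(mags, nSamples, nch, byrow = TRUE)
  if (nrow(mags) != nSamples)
    stop("per-sample magnitude matrix must have nSamples rows")
  withSubstream(seed, "traces", {
    out <- lapply(seq_len(nSamples), function(i) {
      lapply(seq_len(nReplicates), function(r) {
        shape <- .traceShape(truth, nTimepoints, samplingInterval)
        readings <- truth$baseFrequency - outer(mags[i, ], shape) +
          matrix(stats::rnorm(nch * nTimepoints, sd = truth$noiseSd), nch, nTimepoints)
        SensorTrace(readings, samplingInterval = samplingInterval,
          shutterOpenIndex = truth$onsetIndex)
      })
    })
    names(out) <- ids
    out
  })
}

# Unit response shape over reading indices: 0 before onset, rescaled
# exponential rise reaching exactly 1 at 5 time constants, then plateau or
# exponential decay.
.traceShape <- function(truth, nTimepoints, samplingInterval) {
  t <- seq_len(nTimepoints)
  elapsed <- pmax(0, (t - truth$onsetIndex)) * samplingInterval
  sat <- 5 * truth$riseTau
  shape <- ifelse(elapsed >= sat,
    exp(-truth$decayRate * (elapsed - sat)),
    (1 - exp(-elapsed / truth$riseTau)) / (1 - exp(-5)))
  shape[t < truth$onsetIndex] <- 0
  shape
}

#' Long-tailed default descriptor prevalences
#'
#' A prevalence profile shaped like the study cohort's label distribution over
#' 114 molecules: the two most frequent descriptors have about 55 and 52
#' positives, the tail decays geometrically, and most descriptors fall below
#' 12 positives, with a floor of 3.
#'
#' @param nDescriptors vocabulary size.
#' @param cohortSize nominal cohort size the counts refer to (default 114).
#' @return numeric vector of prevalences in (0, 1), decreasing.
#' @export
defaultPrevalences <- function(nDescriptors, cohortSize = 114) {
  head <- c(55, 52)
  tail <- pmax(3, round(47 * 0.87^(seq_len(max(0, nDescriptors - 2)) - 1)))
  counts <- c(head, tail)[seq_len(nDescriptors)]
  counts / cohortSize
}

#' Ground truth for a synthetic cohort
#'
#' Encodes the statistical structure the downstream analysis assumes: a few
#' latent factors shared between the feature modalities and the labels. Each
#' modality observes the factors through its own loading matrix plus noise;
#' each descriptor is a Bernoulli draw whose logit is a prevalence offset plus
#' \code{signalStrength} times a projection of the factors. With
#' \code{signalStrength = 0} labels are independent of all features. The
#' latent dimension defaults to 5, the effective dimensionality observed for
#' e-nose smell vectors.
#'
#' @param prevalences per-descriptor marginal prevalence in (0, 1).
#' @param latentDim number of latent factors (default 5).
#' @param modalityDims named integer vector: features per modality; names in
#'   \code{enose, bfp, cfp, descriptors, spectrum} are kept as provenance.
#' @param signalStrength feature-label coupling (>= 0).
#' @param grouping optional integer vector (one entry per descriptor)
#'   partitioning the vocabulary; descriptors in one group share a latent
#'   direction, so group-level targets are predictable.
#' @param noiseSd feature noise sd around the latent projection. The default
#'   0.1 keeps per-feature measurement noise near 1% of the cross-feature
#'   signal variance, mirroring the very high inter-channel correlation of
#'   QCM membranes, so the synthetic e-nose table has about
#'   \code{latentDim} effective dimensions.
#' @param seed seed for the fixed loadings and descriptor directions.
#' @return list of class "smellbench_cohort_truth".
#' @export
cohortGroundTruth <- function(prevalences, latentDim = 5L,
                              modalityDims = c(enose = 35L, descriptors = 40L),
                              signalStrength = 1, grouping = NULL,
                              noiseSd = 0.1, seed = 1L) {
  if (any(prevalences <= 0 | prevalences >= 1))
    stop("prevalences must lie strictly in (0, 1)")
  if (signalStrength < 0) stop("signal strength must be non-negative")
  if (is.null(names(modalityDims)))
    names(modalityDims) <- paste0("modality", seq_along(modalityDims))
  nDesc <- length(prevalences)
  if (!is.null(grouping)) {
    if (length(grouping) != nDesc)
      stop("grouping must assign every descriptor")
    if (!setequal(unique(grouping), seq_len(max(grouping))))
      stop("grouping must partition the vocabulary into non-empty clusters 1..G")
  }
  withSubstream(seed, "cohort_truth", {
    loadings <- lapply(modalityDims, function(p)
      matrix(stats::rnorm(latentDim * p, sd = 1 / sqrt(latentDim)), latentDim, p))
    if (is.null(grouping)) {
      W <- matrix(stats::rnorm(latentDim * nDesc), latentDim, nDesc)
    } else {
      centers <- matrix(stats::rnorm(latentDim * max(grouping)), latentDim, max(grouping))
      W <- centers[, grouping, drop = FALSE] +
        0.3 * matrix(stats::rnorm(latentDim * nDesc), latentDim, nDesc)
    }
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    structure(list(prevalences = prevalences, latentDim = as.integer(latentDim),
      modalityDims = modalityDims, loadings = loadings, weights = W,
      signalStrength = signalStrength, grouping = grouping, noiseSd = noiseSd),
      class = "smellbench_cohort_truth")
  })
}

#' Generate a synthetic multimodal cohort
#'
#' Draws latent factors for \code{nMolecules} molecules, then produces one
#' [FeatureTable-class] per modality and a [DescriptorMatrix-class] of
#' long-tailed multilabel annotations, all coupled through the factors as
#' described in [cohortGroundTruth()].
#'
#' @param nMolecules cohort size (>= 2).
#' @param vocabulary descriptor names; length must match the truth's
#'   prevalence vector.
#' @param truth a [cohortGroundTruth()].
#' @param seed integer seed (expanded into substreams, so the latent factors,
#'   labels and each modality's noise draw are independent streams).
#' @return list with elements \code{features} (named list of FeatureTable),
#'   \code{labels} (DescriptorMatrix), and \code{latent} (the factor matrix).
#' @export
generateCohort <- function(nMolecules, vocabulary, truth, seed = 1L) {
  stopifnot(is(truth, "smellbench_cohort_truth"))
  if (nMolecules < 2) stop("a cohort needs at least 2 molecules")
  if (!length(vocabulary)) stop("vocabulary must be non-empty")
  if (length(vocabulary) != length(truth$prevalences))
    stop("vocabulary length must match the truth's prevalence vector")
  ids <- sprintf("mol%03d", seq_len(nMolecules))
  Z <- withSubstream(seed, "cohort_latent",
    matrix(stats::rnorm(nMolecules * truth$latentDim), nMolecules, truth$latentDim))
  rownames(Z) <- ids
  logits <- matrix(stats::qlogis(truth$prevalences), nMolecules,
    length(vocabulary), byrow = TRUE) + truth$signalStrength * (Z %*% truth$weights)
  y <- withSubstream(seed, "cohort_labels", {
    m <- matrix(stats::rbinom(length(logits), 1L, stats::plogis(logits)),
      nrow(logits), ncol(logits))
    dimnames(m) <- list(ids, vocabulary)
    m
  })
  features <- lapply(names(truth$modalityDims), function(nm) {
    p <- truth$modalityDims[[nm]]
    X <- withSubstream(seed, paste0("cohort_features_", nm),
      Z %*% truth$loadings[[nm]] +
        truth$noiseSd * matrix(stats::rnorm(nMolecules * p), nMolecules, p))
    rownames(X) <- ids
    colnames(X) <- paste0(nm, seq_len(p))
    FeatureTable(X, provenance = if (nm %in% .provenances) nm else "synthetic")
  })
  names(features) <- names(truth$modalityDims)
  list(features = features, labels = DescriptorMatrix(y), latent = Z)
}

#' Generate a word-embedding fixture with planted group structure
#'
#' Builds unit-norm vectors for a vocabulary with a planted partition: each
#' group gets an orthonormal center and each word is its center scaled by
#' \code{separation} plus standard Gaussian noise, renormalized. With a large
#' separation, within-group cosine similarity strictly exceeds between-group
#' similarity and hierarchical clustering recovers the partition; with
#' \code{separation = 0} the vectors are isotropic noise.
#'
#' @param grouping named integer vector, word -> group index (1..G).
#' @param dim embedding dimension (>= 2; word2vec-scale tables use 300).
#' @param separation center scale relative to unit noise (>= 0).
#' @param seed integer seed.
#' @return numeric matrix, one unit-norm row per word.
#' @export
generateEmbeddingFixture <- function(grouping, dim = 300L, separation = 6, seed = 1L) {
  if (dim < 2) stop("embedding dimension must be at least 2")
  if (separation < 0) stop("separation must be non-negative")
  if (is.null(names(grouping))) stop("grouping must be named by word")
  G <- max(grouping)
  if (dim < G) stop("embedding dimension must be at least the number of groups")
  withSubstream(seed, "embedding_fixture", {
    centers <- qr.Q(qr(matrix(stats::rnorm(dim * G), dim, G)))
    vecs <- t(vapply(grouping, function(g) {
      v <- separation * centers[, g] + stats::rnorm(dim)
      v / sqrt(sum(v^2))
    }, numeric(dim)))
    rownames(vecs) <- names(grouping)
    vecs
  })
}

#' Generate sparse electron-ionization-style mass spectra
#'
#' Each molecule receives \code{ceiling(sparsity * nMzBins)} stick peaks at
#' distinct integer m/z in 1..nMzBins, with exponentially distributed
#' intensities rescaled so the base peak of every spectrum is 999 (the NIST
#' convention). Peak positions are dealt from reshuffled passes over the bin
#' range, so whenever the cohort has at least \code{nMzBins} peak slots in
#' total, the union of observed m/z covers all configured bins.
#'
#' @param nMolecules number of spectra.
#' @param nMzBins size of the m/z range (>= 1).
#' @param sparsity fraction of bins carrying a peak per spectrum, in (0, 1].
#' @param seed integer seed.
#' @param ids molecule ids.
#' @return named list: id -> data.frame(mz, intensity), mz ascending.
#' @export
generateSpectra <- function(nMolecules, nMzBins, sparsity = 0.2, seed = 1L,
                            ids = sprintf("mol%03d", seq_len(nMolecules))) {
  if (nMzBins < 1) stop("nMzBins must be at least 1")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  k <- ceiling(sparsity * nMzBins)
  withSubstream(seed, "spectra", {
    pool <- integer(0)
    out <- lapply(seq_len(nMolecules), function(i) {
      while (length(pool) < k) pool <<- c(pool, sample.int(nMzBins))
      mz <- unique(pool[seq_len(k)])
      pool <<- pool[-seq_len(k)]
      while (length(mz) < k)
        mz <- unique(c(mz, sample.int(nMzBins, k - length(mz))))
      raw <- stats::rexp(k)
      data.frame(mz = sort(mz), intensity = round(raw / max(raw) * 999, 1))
    })
    names(out) <- ids
    out
  })
}
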