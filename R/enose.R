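#' Extract the smell vector of a sensor trace
#'
#' Converts one QCM measurement into its per-membrane base-to-peak frequency
#' change. For each channel independently: the base is the mean of the
#' readings recorded before the shutter opens; the peak is the reading with
#' maximal absolute deviation from that base anywhere in the trace; the
#' channel's entry is |base - peak|. The magnitude convention makes the
#' extraction indifferent to whether adsorption raises or lowers the resonance
#' frequency.
#'
#' @param trace a [SensorTrace-class].
#' @param baselineWindow number of pre-shutter readings used for the base
#'   (default: all readings before \code{shutterOpenIndex}).
#' @return numeric smell vector, one entry per channel (Hz).
#' @examples
#' m <- matrix(1000, 3, 50); m[2, 30] <- 920
#' extractSmellVector(SensorTrace(m, shutterOpenIndex = 10))
#' @export
extractSmellVector <- function(trace, baselineWindow = NULL) {
  stopifnot(is(trace, "SensorTrace"))
  open <- shutterOpenIndex(trace)
  if (open < 2L) stop("no pre-exposure window: shutter opens at the first reading")
  m <- traceMatrix(trace)
  nb <- if (is.null(baselineWindow)) open - 1L else min(baselineWindow, open - 1L)
  if (nb < 1L) stop("baseline window must contain at least one reading")
  pre <- (open - nb):(open - 1L)
  base <- rowMeans(m[, pre, drop = FALSE])
  dev <- abs(m - base)
  apply(dev, 1L, max)
}

#' Average replicate smell vectors
#'
#' Element-wise arithmetic mean of replicate measurements of the same sample
#' (the study protocol averages 3).
#'
#' @param vectors list of equal-length numeric smell vectors (>= 1).
#' @return numeric vector of the same length.
#' @export
averageReplicates <- function(vectors) {
  if (!length(vectors)) stop("at least one smell vector is required")
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L)
    stop("smell vectors have mismatched lengths: ", paste(unique(lens), collapse = ", "))
  Reduce(`+`, vectors) / length(vectors)
}

#' Featurize a cohort of sensor traces
#'
#' Extracts and replicate-averages the smell vector of every molecule,
#' producing the e-nose feature table (one row per molecule, in input order;
#' one column per channel).
#'
#' @param traces named list: molecule id -> list of [SensorTrace-class]
#'   replicates (as produced by [generateTraces()]).
#' @param baselineWindow passed to [extractSmellVector()].
#' @return A [FeatureTable-class] with provenance \code{"enose"}.
#' @export
featurizeCohort <- function(traces, baselineWindow = NULL) {
  if (!length(traces)) stop("no traces to featurize")
  nch <- unique(vapply(traces, function(reps) channelCount(reps[[1]]), 0L))
  if (length(nch) != 1L)
    stop("all traces must share one channel count; found: ", paste(nch, collapse = ", "))
  rows <- lapply(traces, function(reps)
    averageReplicates(lapply(reps, extractSmellVector, baselineWindow = baselineWindow)))
  m <- do.call(rbind, rows)
  rownames(m) <- names(traces)
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  FeatureTable(m, provenance = "enose")
}
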