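#' Read a molecule table
#'
#' Reads a CSV cohort table with one molecule per row. Required columns are
#' \code{id}, \code{cas}, \code{smiles} and \code{descriptors}; the descriptor
#' field holds the odor descriptors of the molecule separated by \code{sep}.
#' Descriptor strings are split, whitespace-trimmed, lower-cased and
#' de-duplicated per molecule at ingest, so the vocabulary is treated
#' case-insensitively (expert annotation sources are inconsistent in case).
#'
#' @param path CSV file with a header row.
#' @param sep separator inside the descriptor field (default ";").
#' @return data.frame with columns id, cas, smiles and a list column
#'   \code{descriptors} of character vectors.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,cas,smiles,descriptors",
#'              "m1,470-82-6,CC1(C)O2CCC1(C)CC2,\"fresh; camphoreous\""), f)
#' readMoleculeTable(f)$descriptors[[1]]
#' @export
readMoleculeTable <- function(path, sep = ";") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "cas", "smiles", "descriptors")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("molecule table is missing required column(s): ",
      paste(missing, collapse = ", "))
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id))
    stop("duplicate molecule id(s): ",
      paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  tab$descriptors <- lapply(strsplit(as.character(tab$descriptors), sep, fixed = TRUE),
    normalizeDescriptors)
  tab[, c("id", "cas", "smiles", "descriptors")]
}

#' Normalize a vector of odor-descriptor strings
#'
#' Trim whitespace, lower-case, drop empties, de-duplicate (first occurrence
#' kept). Idempotent: applying it to its own output changes nothing.
#'
#' @param x character vector of raw descriptor strings.
#' @return normalized character vector.
#' @export
normalizeDescriptors <- function(x) {
  x <- tolower(trimws(x))
  unique(x[nzchar(x)])
}

#' Write a molecule table
#'
#' Inverse of [readMoleculeTable()]: the list column is joined back with
#' \code{sep} so a write/read round trip reproduces the records.
#'
#' @param molecules data.frame as returned by [readMoleculeTable()].
#' @param path output CSV path.
#' @param sep separator for the descriptor field.
#' @export
writeMoleculeTable <- function(molecules, path, sep = ";") {
  out <- molecules
  out$descriptors <- vapply(molecules$descriptors, paste, "", collapse = sep)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor trace
#'
#' Reads one QCM measurement from a CSV file with channels as columns and one
#' row per reading (so a 35-membrane, 30 s scan at 0.1 s is a 300 x 35 grid).
#' The matrix is transposed into the internal channels x timepoints layout.
#'
#' @param path CSV file of numeric readings, channels as columns.
#' @param samplingInterval seconds between readings (default 0.1).
#' @param shutterOpenIndex index of the first exposed reading; required because
#'   the length of the pre-exposure window is a property of the measurement
#'   protocol, not of the file format.
#' @param channels expected channel count; NULL accepts any.
#' @return A [SensorTrace-class].
#' @export
readSensorTrace <- function(path, samplingInterval = 0.1, shutterOpenIndex,
                            channels = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric reading at row %d, column %d of %s",
        bad[1, 1], bad[1, 2], path))
    stop("trace file contains non-numeric readings: ", path)
  }
  if (!is.null(channels) && ncol(m) != channels)
    stop(sprintf("expected %d channels but found %d in %s", channels, ncol(m), path))
  SensorTrace(t(m), samplingInterval = samplingInterval,
    shutterOpenIndex = shutterOpenIndex)
}

#' Write a sensor trace
#'
#' @param trace a [SensorTrace-class].
#' @param path output CSV path (channels as columns).
#' @export
writeSensorTrace <- function(trace, path) {
  m <- t(traceMatrix(trace))
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  .writeNumericCsv(as.data.frame(m), path)
  invisible(path)
}

#' Read a word-embedding table
#'
#' Reads word2vec-style text: one \code{word v1 v2 ... vD} line per word, with
#' an optional leading \code{count dim} header line which is consumed. All
#' vectors must share one dimension. A duplicated word keeps its last
#' occurrence, with a warning.
#'
#' @param path embedding text file.
#' @return numeric matrix, one row per word (rownames = words).
#' @export
readEmbeddingTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L)
    stop("ragged embedding file: vector lengths ", paste(unique(dims), collapse = ", "))
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[[1]])))
  if (anyNA(vecs)) stop("non-numeric vector entry in embedding file")
  if (anyDuplicated(words)) {
    warning("duplicate word(s) in embedding file; keeping last occurrence: ",
      paste(unique(words[duplicated(words)]), collapse = ", "))
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]; vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- words
  vecs
}

#' Write a word-embedding table
#'
#' @param embedding matrix with words as rownames.
#' @param path output path; written in word2vec text format with a header line.
#' @export
writeEmbeddingTable <- function(embedding, path) {
  header <- paste(nrow(embedding), ncol(embedding))
  body <- vapply(seq_len(nrow(embedding)), function(i) {
    paste(rownames(embedding)[i],
      paste(formatC(embedding[i, ], digits = 17, format = "g"), collapse = " "))
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a feature table
#'
#' Feature tables are CSVs with an \code{id} first column and one column per
#' feature. Provenance is not stored in the CSV; it is supplied on read.
#'
#' @param path CSV path.
#' @param provenance provenance tag for the resulting [FeatureTable-class].
#' @return [FeatureTable-class] for the reader; invisible path for the writer.
#' @export
readFeatureTable <- function(path, provenance = "synthetic") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "id") stop("feature table must start with an id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("feature table contains non-numeric values")
  rownames(m) <- as.character(tab$id)
  FeatureTable(m, provenance = provenance)
}

#' @rdname readFeatureTable
#' @param table a [FeatureTable-class].
#' @export
writeFeatureTable <- function(table, path) {
  m <- featureMatrix(table)
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
  .writeNumericCsv(df, path)
  invisible(path)
}

#' Read / write a descriptor label matrix
#'
#' @param path CSV path with an \code{id} first column and one binary column
#'   per descriptor.
#' @return [DescriptorMatrix-class] for the reader.
#' @export
readDescriptorMatrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "id") stop("label table must start with an id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$id)
  DescriptorMatrix(m)
}

#' @rdname readDescriptorMatrix
#' @param labels a [DescriptorMatrix-class].
#' @export
writeDescriptorMatrix <- function(labels, path) {
  m <- labelMatrix(labels)
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write one mass spectrum
#'
#' A spectrum is a two-column CSV of (mz, intensity) stick peaks at unit m/z
#' resolution.
#'
#' @param path CSV path.
#' @return data.frame(mz, intensity) for the reader.
#' @export
readSpectrum <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(tab)))
    stop("spectrum file needs mz and intensity columns")
  if (any(tab$mz <= 0) || any(tab$mz != round(tab$mz)))
    stop("m/z values must be positive integers")
  if (any(tab$intensity < 0)) stop("intensities must be non-negative")
  data.frame(mz = as.integer(tab$mz), intensity = as.numeric(tab$intensity))
}

#' @rdname readSpectrum
#' @param spectrum data.frame(mz, intensity).
#' @export
writeSpectrum <- function(spectrum, path) {
  .writeNumericCsv(spectrum, path)
  invisible(path)
}

#' Write an analysis result with its JSON sidecar
#'
#' Serializes an [EvaluationResult-class], [ComparisonResult-class],
#' [GroupEvaluation-class] or [CompositionResult-class] as a flat CSV (one row
#' per descriptor, group or cluster; fold-level values are kept as columns)
#' plus a \code{<path>.json} sidecar holding the CV plan / configuration and
#' seed so a run can be reproduced.
#'
#' @param result the result object.
#' @param path output CSV path; the sidecar is written next to it.
#' @return invisible path.
#' @export
writeResults <- function(result, path) {
  sidecar <- list(class = class(result)[[1]])
  if (is(result, "EvaluationResult")) {
    df <- .evaluationFrame(result)
    sidecar$plan <- cvPlan(result)
  } else if (is(result, "GroupEvaluation")) {
    df <- result@rates
    sidecar$plan <- cvPlan(result@evaluation)
  } else if (is(result, "ComparisonResult")) {
    df <- data.frame(statistic = result@statistic, p_value = result@pValue,
      n_pairs = result@nPairs, mean_difference = result@meanDifference,
      degenerate = result@degenerate)
  } else if (is(result, "CompositionResult")) {
    p <- result@percentages
    df <- data.frame(descriptor = rownames(p), total_positives = result@positiveTotals,
      p, check.names = FALSE)
    colnames(df)[-(1:2)] <- paste0("cluster_", seq_len(ncol(p)))
  } else stop("unsupported result class: ", class(result)[[1]])
  .writeNumericCsv(df, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
    digits = NA, null = "null")
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#'
#' @param path CSV path.
#' @return data.frame with the table; the sidecar (if present) is attached as
#'   attribute \code{"sidecar"}.
#' @export
readResults <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(df, "sidecar") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df
}

.evaluationFrame <- function(result) {
  f1 <- foldF1(result); rec <- foldRecall(result)
  df <- data.frame(target = rownames(f1), mean_f1 = rowMeans(f1),
    mean_recall = rowMeans(rec))
  ff <- as.data.frame(f1); names(ff) <- paste0("f1_fold_", seq_len(ncol(f1)))
  fr <- as.data.frame(rec); names(fr) <- paste0("recall_fold_", seq_len(ncol(rec)))
  cbind(df, ff, fr)
}

# CSV writer that prints reals with 17 significant digits so write/read round
# trips are exact for doubles (and bit-identical for integers).
.writeNumericCsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- trimws(formatC(df[[j]], digits = 17, format = "g"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
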