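#' Fingerprint specification
#'
#' Parameters of a Morgan (extended-connectivity) fingerprint. The defaults,
#' radius 3 folded to 1024 bits, correspond to an ECFP6 fingerprint (the
#' diameter is twice the radius).
#'
#' @param radius neighborhood radius (>= 0).
#' @param nBits folded length; must be a power of two.
#' @param kind "bit" records substructure presence, "count" occurrence counts.
#' @return list of class "smellbench_fp_spec".
#' @export
fingerprintSpec <- function(radius = 3L, nBits = 1024L, kind = c("bit", "count")) {
  kind <- match.arg(kind)
  if (radius < 0) stop("radius must be non-negative")
  if (nBits < 1 || bitwAnd(nBits, nBits - 1L) != 0L)
    stop("nBits must be a power of two")
  structure(list(radius = as.integer(radius), nBits = as.integer(nBits), kind = kind),
    class = "smellbench_fp_spec")
}

.backendCache <- new.env(parent = emptyenv())

#' Is the RDKit chemistry backend available?
#'
#' The fingerprint and molecular-descriptor backends shell out to a Python
#' interpreter with RDKit importable. The check result is cached per session.
#'
#' @return TRUE or FALSE.
#' @export
rdkitAvailable <- function() {
  if (!is.null(.backendCache$rdkit)) return(.backendCache$rdkit)
  py <- Sys.which("python")
  ok <- nzchar(py) &&
    system2(py, c("-c", shQuote("import rdkit")), stdout = FALSE, stderr = FALSE) == 0L
  .backendCache$rdkit <- ok
  ok
}

.rdkitScript <- function() {
  path <- system.file("python", "rdkit_backend.py", package = "smellbench")
  if (!nzchar(path)) stop("rdkit_backend.py not found in the installed package")
  path
}

.runRdkit <- function(args, molecules) {
  if (!rdkitAvailable())
    stop("chemistry backend unavailable: no Python interpreter with RDKit importable")
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)))
  utils::write.csv(data.frame(id = molecules$id, smiles = molecules$smiles),
    infile, row.names = FALSE)
  err <- tempfile()
  status <- system2(Sys.which("python"),
    c(shQuote(.rdkitScript()), args, shQuote(infile), shQuote(outfile)),
    stdout = FALSE, stderr = err)
  if (status != 0L) {
    msg <- paste(readLines(err, warn = FALSE), collapse = "\n")
    stop("chemistry backend failed: ", msg)
  }
  tab <- utils::read.csv(outfile, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m[molecules$id, , drop = FALSE]
}

#' RDKit Morgan-fingerprint backend
#'
#' @return a backend function(molecules, spec) -> id x nBits matrix, suitable
#'   for [computeFingerprints()].
#' @export
rdkitFingerprintBackend <- function() {
  function(molecules, spec) {
    .runRdkit(c("fp", spec$kind, spec$radius, spec$nBits), molecules)
  }
}

#' RDKit molecular-descriptor backend
#'
#' Computes the full RDKit descriptor list (physicochemical and topological
#' properties) per molecule. Which descriptors exist, and hence the table
#' width, depends on the backend version; tests pin the oracle to the
#' installed version.
#'
#' @return a backend function(molecules) -> id x descriptor matrix.
#' @export
rdkitDescriptorBackend <- function() {
  function(molecules) .runRdkit("desc", molecules)
}

#' Compute Morgan fingerprints for a cohort
#'
#' @param molecules molecule data.frame from [readMoleculeTable()] (needs id
#'   and smiles).
#' @param spec a [fingerprintSpec()].
#' @param backend a fingerprint backend; default RDKit via Python.
#' @return A [FeatureTable-class] with provenance \code{"bfp"} or \code{"cfp"};
#'   rows follow the molecule-table order.
#' @export
computeFingerprints <- function(molecules, spec = fingerprintSpec(),
                                backend = rdkitFingerprintBackend()) {
  stopifnot(is(spec, "smellbench_fp_spec"))
  m <- backend(molecules, spec)
  if (spec$kind == "bit" && !all(m %in% c(0, 1)))
    stop("bit fingerprint backend returned non-binary values")
  if (any(m < 0) || any(m != round(m)))
    stop("fingerprint backend returned negative or non-integer counts")
  FeatureTable(m, provenance = if (spec$kind == "bit") "bfp" else "cfp")
}

#' Compute the numeric molecular-descriptor table
#'
#' Runs the descriptor backend and then applies the cleanup rule: columns that
#' are non-numeric, entirely missing, or otherwise uncomputable are dropped
#' (with a message naming them), and remaining sporadic missing values are
#' median-imputed so the table is all-numeric.
#'
#' @param molecules molecule data.frame (id, smiles).
#' @param backend a descriptor backend; default RDKit via Python.
#' @return A [FeatureTable-class] with provenance \code{"descriptors"}.
#' @export
computeDescriptorTable <- function(molecules, backend = rdkitDescriptorBackend()) {
  raw <- backend(molecules)
  m <- cleanNumericTable(raw)
  FeatureTable(m, provenance = "descriptors")
}

#' Keep only usable numeric columns
#'
#' Cleanup rule shared by the descriptor featurization: non-numeric columns
#' and columns with no finite value are dropped (a message lists them);
#' remaining non-finite cells are imputed with the column median.
#'
#' @param x matrix or data.frame.
#' @return all-numeric, all-finite matrix.
#' @export
cleanNumericTable <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  numeric_ok <- vapply(df, function(col) is.numeric(col) || is.logical(col), TRUE)
  if (any(!numeric_ok))
    message("dropping non-numeric column(s): ",
      paste(names(df)[!numeric_ok], collapse = ", "))
  df <- df[, numeric_ok, drop = FALSE]
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  allBad <- apply(m, 2, function(col) !any(is.finite(col)))
  if (any(allBad))
    message("dropping column(s) with no finite values: ",
      paste(colnames(m)[allBad], collapse = ", "))
  m <- m[, !allBad, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    bad <- !is.finite(m[, j])
    if (any(bad)) m[bad, j] <- stats::median(m[is.finite(m[, j]), j])
  }
  if (!is.null(rownames(x))) rownames(m) <- rownames(x)
  m
}

#' Build the cohort mass-spectrum matrix
#'
#' Places every spectrum on a common integer m/z axis: by default the sorted
#' union of m/z observed anywhere in the cohort; alternatively a fixed range.
#' Cells without a peak are 0, so the matrix conserves total intensity.
#'
#' @param spectra named list: molecule id -> data.frame(mz, intensity).
#' @param mzRange optional integer vector giving a fixed axis (e.g.
#'   \code{1:212}); NULL means the observed union.
#' @return list with \code{table}, a [FeatureTable-class] with provenance
#'   \code{"spectrum"}, and \code{mzAxis}, the sorted integer axis.
#' @export
buildSpectrumMatrix <- function(spectra, mzRange = NULL) {
  if (!length(spectra)) stop("no spectra supplied")
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    if (any(sp$mz <= 0) || any(sp$mz != round(sp$mz)))
      stop("m/z values must be positive integers (molecule ", id, ")")
    if (any(sp$intensity < 0))
      stop("negative intensity in spectrum of molecule ", id)
  }
  axis <- if (is.null(mzRange)) {
    sort(unique(unlist(lapply(spectra, `[[`, "mz"))))
  } else sort(unique(as.integer(mzRange)))
  m <- matrix(0, length(spectra), length(axis),
    dimnames = list(names(spectra), paste0("mz", axis)))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    idx <- match(sp$mz, axis)
    keep <- !is.na(idx)
    m[i, idx[keep]] <- m[i, idx[keep]] + sp$intensity[keep]
  }
  list(table = FeatureTable(m, provenance = "spectrum"), mzAxis = axis)
}
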