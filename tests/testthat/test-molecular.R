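# The chemistry backend (Python RDKit) is part of the supported stack; the
# count/bit oracle values below were pinned from a one-off run of RDKit
# 2024.09.2 (Morgan generator, radius 3, 1024 bits).

test_that("Morgan fingerprints match the pinned backend oracle", {
  mol <- data.frame(id = c("methane", "ethanol"), cas = NA,
    smiles = c("C", "CCO"))
  cfp <- computeFingerprints(mol, fingerprintSpec(kind = "count"))
  expect_identical(provenance(cfp), "cfp")
  expect_equal(dim(featureMatrix(cfp)), c(2, 1024))
  expect_equal(sum(featureMatrix(cfp)["methane", ]), 1)

  bfp <- computeFingerprints(mol, fingerprintSpec(kind = "bit"))
  expect_identical(provenance(bfp), "bfp")
  expect_true(all(featureMatrix(bfp) %in% c(0, 1)))
  expect_equal(sum(featureMatrix(bfp)["ethanol", ]), 6)
})

test_that("fingerprints are invariant to SMILES rewriting and deterministic", {
  mol <- data.frame(id = c("a", "b", "c"), cas = NA,
    smiles = c("CCO", "OCC", "CCO"))
  fp <- featureMatrix(computeFingerprints(mol, fingerprintSpec(kind = "count")))
  expect_equal(unname(fp["a", ]), unname(fp["b", ]))
  expect_equal(unname(fp["a", ]), unname(fp["c", ]))
})

test_that("unparseable SMILES raise an error naming the molecule", {
  mol <- data.frame(id = c("ok", "broken"), cas = NA, smiles = c("CCO", "notsmiles("))
  expect_error(computeFingerprints(mol), "broken")
})

test_that("fingerprint spec validates its parameters", {
  expect_error(fingerprintSpec(nBits = 1000), "power of two")
  expect_error(fingerprintSpec(radius = -1), "non-negative")
})

test_that("descriptor backend width matches the pinned RDKit version oracle", {
  mol <- data.frame(id = "ethanol", cas = NA, smiles = "CCO")
  dt <- computeDescriptorTable(mol)
  expect_identical(provenance(dt), "descriptors")
  expect_equal(ncol(featureMatrix(dt)), 210)
  expect_equal(featureMatrix(dt)["ethanol", "MolWt"], 46.069, tolerance = 1e-6)
})

test_that("descriptor cleanup drops non-numeric and all-missing columns", {
  raw <- data.frame(a = c(1, 2), b = c("x", "y"), c = c(NA_real_, NA_real_),
    d = c(1, NA))
  rownames(raw) <- c("m1", "m2")
  expect_message(m <- cleanNumericTable(raw), "non-numeric.*b")
  expect_message(cleanNumericTable(raw), "no finite values.*c")
  m <- suppressMessages(cleanNumericTable(raw))
  expect_equal(colnames(m), c("a", "d"))
  expect_equal(m["m2", "d"], 1)   # sporadic NA median-imputed
})

test_that("spectrum matrices use the sorted union axis with zero fill", {
  spectra <- list(
    m1 = data.frame(mz = 50L, intensity = 10),
    m2 = data.frame(mz = 60L, intensity = 5))
  res <- buildSpectrumMatrix(spectra)
  expect_equal(res$mzAxis, c(50L, 60L))
  expect_equal(unname(featureMatrix(res$table)),
    matrix(c(10, 0, 0, 5), 2, byrow = TRUE))
  expect_identical(provenance(res$table), "spectrum")

  single <- buildSpectrumMatrix(spectra["m1"])
  expect_equal(ncol(featureMatrix(single$table)), 1)
})

test_that("spectrum matrices conserve total intensity and validate input", {
  spectra <- generateSpectra(15, 80, sparsity = 0.3, seed = 8)
  res <- buildSpectrumMatrix(spectra)
  expect_equal(sum(featureMatrix(res$table)),
    sum(unlist(lapply(spectra, `[[`, "intensity"))))
  expect_identical(rownames(featureMatrix(res$table)), names(spectra))

  fixed <- buildSpectrumMatrix(spectra, mzRange = 1:80)
  expect_equal(ncol(featureMatrix(fixed$table)), 80)

  bad <- list(m1 = data.frame(mz = 10L, intensity = -2))
  expect_error(buildSpectrumMatrix(bad), "negative intensity")
})
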