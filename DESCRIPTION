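Package: smellbench
Title: Benchmarking Odorant Featurizations for Odor Descriptor Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing featurizations of odorant molecules -- quartz
    crystal microbalance (QCM) e-nose smell vectors, bit and count Morgan
    fingerprints, numeric molecular descriptors, and electron-ionization mass
    spectra -- on odor-descriptor prediction tasks. Provides e-nose trace
    featurization (base-to-peak frequency change per receptor membrane),
    min-max normalization and variance-threshold PCA reduction, per-descriptor
    one-class and binary SVM evaluation under repeated stratified k-fold
    cross-validation with F1 and recall, paired t-test comparison of feature
    sets, word-embedding-based clustering of odor descriptors into groups with
    group-level targets, elbow-selected molecule clustering, and per-cluster
    descriptor composition percentages. A synthetic-data generator with known
    ground truth (sensor traces, multimodal feature tables sharing latent
    factors with long-tailed multilabel annotations, embedding fixtures with
    planted group structure, sparse mass spectra) makes every stage testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'synthetic.R'
    'enose.R'
    'molecular.R'
    'preprocessing.R'
    'prediction.R'
    'grouping.R'
    'composition.R'
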