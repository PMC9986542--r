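Package: redoxflim
Title: Synthetic Autofluorescence Metabolic Imaging of Brain Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for label-free metabolic imaging
    of brain tumor tissue. Provides a photophysical forward model for
    NAD(P)H/FMN/FAD autofluorescence emission spectra and frequency-domain
    flavin fluorescence lifetimes, spectral metrics (optical redox ratio and
    the protein-bound FMN to FAD peak ratio), a calibrated synthetic cohort
    generator for a five-group surgical cohort, nonparametric cohort
    statistics, and SMOTE-balanced repeated stratified cross-validation for
    multi-class tumor-entity classification with per-class sensitivity and
    specificity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    class,
    e1071,
    xgboost,
    randomForest,
    ranger,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
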