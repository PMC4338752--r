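Package: ecogseg
Title: Segmental-Feature Decoding of Speech from Electrocorticographic
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for mapping the cortical representation of
    speech segmental features (place and manner of articulation, voicing,
    consonant/vowel class) from multi-channel electrocorticographic (ECoG)
    recordings of continuous speech. Implements the gamma-band (70-170 Hz)
    log-power signal chain with per-grid common-average referencing,
    phoneme-locked epoch extraction and time binning, minimum-redundancy
    maximum-relevance (mRMR) feature selection, Ledoit-Wolf shrinkage
    regularized linear discriminant analysis with stratified cross-validation,
    ROC-AUC significance via the Hanley-McNeil standard error with
    false-discovery-rate correction, and spatial/temporal activation-index
    mapping. A synthetic-data generator with known ground truth (1/f
    background, line noise, per-grid common mode, phoneme-locked gamma bursts)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
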