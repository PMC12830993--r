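Package: pirlms
Title: Rejection-Capable PCA-LDA Classification of Ambient Mass-Spectrometry
    Tissue Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 10-second tissue classification from ambient
    laser-ablation mass spectrometry, built around the problem of detecting
    lymphoproliferative "imposter" outgrowths among solid-tumour
    patient-derived xenografts. Provides a synthetic scan-stream generator
    with per-specimen random effects and injected bad-data modes, spectral
    preprocessing (sampling-event recognition, lock-mass correction at m/z
    717.5070, 0.1-Da binning over 100-1000 Da, total-ion-count
    normalization, quality control), a PCA-LDA classifier with a
    Mahalanobis-distance rejection option, specimen-grouped stratified
    cross-validation with a permutation-label null and a SMOTE variant,
    blind-set evaluation with sensitivity/specificity/duty-cycle accounting,
    and diagnostics (UMAP embedding, LDA jitter data, Pearson feature
    correlation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
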