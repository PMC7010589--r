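Package: riemfc
Title: Riemannian Kernel PCA Classification of Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and classification for ROI-level functional
    connectivity matrices using kernel principal component analysis with a
    log-Euclidean (Riemannian) kernel on regularized graph Laplacians.
    Includes gradient-boosted-tree classification with stratified
    cross-validation, pre-image reconstruction that maps classifier feature
    importance back to an importance matrix over brain connections,
    seed-based connectivity statistics (Fisher-Z maps, covariate-adjusted
    group tests, symptom-severity regression), and a synthetic cohort
    generator with planted group differences for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    xgboost,
    e1071
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
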