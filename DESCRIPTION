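Package: readerbench
Title: Multi-Reader Multi-Case Benchmarking of Radiologists and AI Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-reader multi-case (MRMC) diagnostic accuracy
    studies that benchmark groups of human readers against stand-alone AI
    classifiers on a shared case set. Aggregates 5-point Likert ratings into
    per-case consensus scores with exclusion rules, calibrates and ensembles
    continuous AI abnormality scores, and performs ROC inference: empirical
    AUROC with DeLong confidence intervals, binormal ROC smoothing for
    display, Youden-index operating points with exact binomial confidence
    intervals, and paired permutation tests for AUROC differences. Includes
    a synthetic study generator (equal-variance binormal latent model) so
    the full pipeline is testable without access to reader-study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
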