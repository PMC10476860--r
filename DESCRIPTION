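Package: breathpanel
Title: Breath VOC Marker-Panel Discovery for Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering volatile organic compound (VOC) marker panels
    in exhaled-breath GC-MS data from colorectal cancer screening cohorts.
    Provides a synthetic cohort generator with known ground truth (log-normal
    peak areas, planted class markers, instrument batch effects, detection
    dropout), a chromatogram preprocessing chain (smoothing, asymmetric
    least-squares baseline correction, peak picking, retention-time alignment,
    total-intensity normalization, class-prevalence filtering, Pareto or unit
    scaling), empirical-Bayes batch correction with surrogate variable analysis,
    a from-scratch Isolation Forest for one-class screening and representative
    train/test splitting, Random-Forest marker-panel selection by iterated
    permutation importance with out-of-bag proximity ordination (PCoA), and a
    hierarchical midlevel-fusion three-class model evaluated by weighted
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
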