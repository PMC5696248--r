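Package: mrmpanel
Title: Plasma Biomarker Panel Development from Targeted MRM Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing multi-marker diagnostic panels from
    targeted multiple-reaction-monitoring (MRM) plasma proteomics.
    Covers stable-isotope-dilution peptide quantitation from
    transition-level peak areas, verification-stage quality filters
    (replicate CV, relative-level reference range, interference
    detection on light/heavy transition-ratio discordance, center and
    batch confounder screening, single-marker AUC screening), anchored
    combinatorial panel search with support-vector-machine
    classification and stratified cross-validation, paired ROC
    comparison (DeLong's test, McNemar's test at fixed specificity),
    positive predictive value under a population prevalence, and
    scenario-based validation reports. Includes a synthetic
    multi-center case-control cohort generator with ground-truth
    labels for end-to-end benchmarking of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
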