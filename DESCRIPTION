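Package: hipporad
Title: Hippocampal Radiomics Pipeline for Case-Control MRI Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Radiomic analysis of masked 3D structural MR volumes for
    case-control classification, built around the hippocampus in amnestic
    mild cognitive impairment. Extracts a 385-feature catalog (first-order
    histogram statistics, form-factor shape descriptors, gray-level
    co-occurrence matrix and Haralick texture statistics at offsets 1, 4
    and 7, and gray-level run-length matrix features), applies a
    three-stage feature-selection cascade (univariate t-test plus rank
    test, Spearman redundancy filter, cross-validated LASSO), and fits
    logistic-regression classifiers evaluated over repeated stratified
    train/test splits. Includes a synthetic textured-volume cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
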