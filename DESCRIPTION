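Package: leakcv
Title: Benchmarking Data Leakage in Connectome-Based Predictive Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how data leakage distorts cross-validated
    prediction from brain connectomes. Implements the gold-standard
    pipeline (family-aware splits, cross-validated ComBat site
    harmonization, train-fitted covariate regression, within-fold feature
    selection, nested ridge or CPM models) together with explicitly leaky
    variants (full-data feature selection, full-data ComBat and covariate
    regression, duplicated subjects, family-ignorant splits), paired
    performance deltas (change in Pearson's r and cross-validation
    R-squared, q2), coefficient and subnetwork comparisons, subsampling
    experiments, and a synthetic connectome generator with controllable
    effect size, family, site and covariate structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, e1071
Suggests: testthat (>= 3.0.0), sva, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
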