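Package: petngtdm
Title: Dual-Time-Point PET Texture Analysis of Pulmonary Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise neighborhood gray-tone difference matrix (NGTDM)
    texture analysis of dual-time-point FDG-PET lesion volumes. Extracts
    coarseness, contrast and busyness from early and delayed PET images of
    solitary pulmonary nodules, applies metabolic-volume and SUVmax
    inclusion filters, and evaluates benign/malignant discrimination with
    ROC analysis (closest-to-corner operating point), Wilcoxon rank-sum
    tests, Pearson correlations with reader scores, and stratified 11-fold
    cross-validation. Includes a synthetic dual-time-point phantom
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
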