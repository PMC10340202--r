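Package: ranovol
Title: RANO Bidirectional Measurement and Volumetric Growth Detection for
    Longitudinal Glioma Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess lower-grade glioma progression on longitudinal
    MRI-derived tumor masks. Implements automated RANO bidirectional
    measurement (longest axial diameter and its longest perpendicular
    diameter on the largest tumor cross-section) with the 25 percent
    product-growth rule and multi-operator consensus; slice-stack
    volumetrics with statistical change-of-point growth detection; a
    non-negative matrix factorization segmentation sketch with gray-level
    thresholding; reproducibility statistics (Pearson agreement,
    coefficient of variance, Bland-Altman, Cohen's kappa); timing-based
    confusion and ROC/AUC accuracy evaluation with diagnosis-delay
    analysis; and a synthetic longitudinal tumor cohort generator with
    known growth change-points so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pROC,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
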