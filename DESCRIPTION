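Package: plsrdcv
Title: PLS-DA with Repeated Double Cross-Validation for Untargeted
    Metabolomics Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for two-class discrimination on untargeted
    LC-MS peak-area tables, as used in urinary metabolomics studies of prostate
    carcinoma versus benign hyperplasia. Provides QC-anchored preprocessing
    (blank/carry-over filtering, QC-based signal drift correction, QC presence
    and relative-standard-deviation filters, creatinine normalization,
    autoscaling, multi-block Frobenius scaling), a NIPALS PLS-DA classifier,
    a repeated double cross-validation engine with nonparametric confidence
    intervals and permutation testing, rank-product plus VIP variable
    selection, ROC/AUROC estimation averaged over cross-validation
    repetitions, PCA-based sample diagnostics (Hotelling's T2, Q residuals,
    contributions), and a synthetic feature-table generator with planted
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
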