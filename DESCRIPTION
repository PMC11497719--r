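Package: plasmapanel
Title: Multimarker Plasma Biomarker Panels for Dementia Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Development, validation and clinical interpretation of
    multimarker blood tests for dementia diagnosis from plasma P-tau181,
    GFAP, NfL and the Abeta42/40 ratio. Provides cohort data management
    with amyloid-status adjudication from CSF and PET cutoff rules,
    Passing-Bablok regression for assay-lot harmonization, bootstrapped
    LASSO marker selection with cross-validated penalty tuning, logistic
    diagnostic models per clinical question with cross-validated ROC-AUC,
    Youden-index marker thresholds and two-cutoff likelihood zones,
    external validation via cohort-membership models, calibration-in-the-
    large, calibration slope and TRIPOD-style calibration curves, UpSet
    and probability-density interpretation graphics for individual
    patients, and a Gaussian-copula lognormal synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    graphics,
    grDevices,
    utils,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
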