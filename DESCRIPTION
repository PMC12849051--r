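Package: ovatriage
Title: Diagnostic Accuracy of Ovarian Cancer Triage Tests in Premenopausal Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Head-to-head diagnostic test accuracy analysis for ovarian cancer
    triage in premenopausal women presenting with non-specific symptoms.
    Implements six published risk prediction scores (Risk of Malignancy Index 1,
    Risk of Malignancy Algorithm, IOTA ADNEX, IOTA simple rules and its risk
    model, serum CA 125) plus a post hoc ORADS category mapping; derives
    primary and secondary outcome labels from a surgical/follow-up reference
    standard; builds 2x2 tables with explicit missing- and inconclusive-result
    policies; computes sensitivity, specificity and predictive values with
    exact Clopper-Pearson intervals; compares paired tests with the exact
    McNemar test and asymptotic difference intervals; assesses discrimination
    (C index with DeLong intervals) and calibration (decile plots,
    recalibration slope); handles missing predictors with multiple imputation
    by chained equations and Rubin-rules pooling; and ships a synthetic cohort
    generator emulating the study population so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
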