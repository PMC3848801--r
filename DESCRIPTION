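Package: ovatriage
Title: Symptom and Tumor-Marker Triage of Ovarian Masses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Preoperative triage of women with adnexal (ovarian) masses from
    patient-reported symptoms and serum tumor markers. Implements the
    frequency/onset symptom dichotomization rule, Ward agglomerative
    clustering of binary symptom indicators, the six canonical symptom
    clusters and the Symptom Index (SI), the Risk of Ovarian Malignancy
    Algorithm (ROMA) with menopause-stratified CA125/HE4/ROMA cutoffs, and
    the full diagnostic-accuracy toolkit (sensitivity/specificity with
    Wilson intervals, predictive values, crude odds ratios, chi-square and
    Fisher tests, ROC AUC with DeLong variance and paired DeLong
    comparison, Youden-optimal cutoffs). A seeded synthetic-cohort
    generator with group-specific correlated binary symptoms and
    group-conditional log-normal marker models makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
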