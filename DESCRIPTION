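Package: insomniaphen
Title: Rule-Based EMR Phenotyping of Physician-Documented Insomnia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies patients with physician-documented insomnia from
    electronic medical record (EMR) extracts by combining structured data
    (ICD-9 billing codes, pharmacy prescriptions, utilization tallies) with
    rule-based matching of non-negated sleep-disorder expressions in
    narrative notes. Ships the published seven-variable logistic scoring
    equation with its specificity-anchored decision threshold, and the full
    model-development protocol: adaptive-LASSO logistic regression over
    variable-subset configurations, threshold calibration to a target
    specificity, bootstrap AUROC confidence intervals, and a permutation
    overfitting check. A synthetic EMR corpus generator with recorded
    ground truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
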