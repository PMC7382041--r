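Package: predsig
Title: Predictive Gene-Expression Signatures for Two-Arm Survival Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of predictive (treatment-by-expression
    interaction) gene-expression signatures of progression-free survival in
    two-arm clinical trials. Provides dimensional reduction by molecular-subtype
    centroid correlation (subC), mechanism-of-action gene lists (MOA) and
    supervised principal components (SPC); interaction Cox models and the
    differential log-hazard-ratio biomarker; hazard-ratio ROC curves, the area
    between curves, bootstrap predictive risk, permutation controls, patient
    selection matrices and objective-function threshold optimization; plus a
    synthetic two-arm trial generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
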