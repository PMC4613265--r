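Package: nmrscreen
Title: First-Trimester NMR Metabolomics Screening for Hypertensive
    Pregnancy Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for predicting preeclampsia and
    gestational hypertension from first-trimester 1H NMR metabolic
    profiles of urine and serum. Provides spectral preprocessing
    (region extraction, interval cross-correlation alignment,
    probabilistic quotient normalization, pareto scaling), PLS-DA
    classification with variable importance in projection (VIP) scores,
    competitive adaptive reweighted sampling (CARS) variable selection,
    stratified double cross-validation with permutation testing, and
    logistic risk models that combine urinary metabolite ratios with
    maternal characteristics. Includes a synthetic cohort generator
    with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics
Config/testthat/edition: 3
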