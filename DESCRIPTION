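Package: lungqct
Title: Quantitative CT Analysis of Airways, Lung Parenchyma and Pulmonary
    Vessels with Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative computed-tomography (QCT) metrics of occupational
    lung disease severity, exercised on synthetic CT phantoms and synthetic
    cohorts with known ground truth.  Extracts 1-D airway centerlines from
    airway masks, labels the bronchial tree anatomically, and measures
    bifurcation angle, hydraulic diameter, wall thickness and circularity
    per branch; classifies lung voxels into Hounsfield-unit density classes
    (emphysema, normal, ground-glass opacity, semi consolidation,
    consolidation, fibrosis); bins pulmonary vessel volume by
    cross-sectional area (BV1/BV5/BV10 over TBV); and runs the cohort
    statistics chain: logistic propensity scores, two-stage greedy
    one-to-one matching with a caliper, standardized-mean-difference
    balance tables, expectation-maximization imputation of missing
    structural metrics, Kruskal-Wallis and Mann-Whitney tests with
    Bonferroni correction, and Pearson correlation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
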