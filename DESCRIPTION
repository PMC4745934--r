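Package: pcps
Title: Prognostic Scoring and Diagnostic Evaluation for Inoperable Gastric Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements inflammation- and nutrition-based prognostic scores for
    inoperable gastric adenocarcinoma cohorts: the Glasgow Prognostic Score
    (CRP/albumin) and a prealbumin/CRP based prognostic score (PCPS), together
    with ROC analysis and Youden-index cut-point selection, full binary
    diagnostic evaluation (sensitivity, specificity, predictive values,
    likelihood ratios) with Wilson, Simel log-method and Hanley-McNeil
    confidence intervals, group-comparison statistics (pooled t, Mann-Whitney,
    exact chi-square, Kruskal-Wallis), a synthetic biomarker cohort generator
    parameterised by published group summaries, and a rounding-aware integer
    confusion-matrix reconstruction that recovers exact 2x2 tables from
    published rounded percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
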