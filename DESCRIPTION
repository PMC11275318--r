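Package: dynosurv
Title: Dynamic Prediction of Overall Survival by Landmarking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Landmarking analysis for dynamic overall-survival prediction in
    high-grade osteosarcoma cohorts. Builds stacked landmark data sets over a
    grid of prediction times, fits a proportional landmark supermodel by
    pseudo partial likelihood with delayed entry, Breslow ties and
    cluster-robust variance, and turns the fit into time-varying hazard
    ratios and dynamic fixed-window death probabilities. Includes a
    multistate synthetic cohort generator with known ground truth,
    sliding-window concordance validation with leave-one-out
    cross-validation, a heuristic shrinkage factor, reverse Kaplan-Meier
    median follow-up, and multiple imputation with Rubin's-rules pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
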