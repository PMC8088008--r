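Package: gestage
Title: First-Trimester Gestational Age Dating from Crown-Rump Length
Version: 0.1.0
Authors@R: person("GARBH", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for first-trimester pregnancy dating from ultrasound
    crown-rump length (CRL). Ships a registry of published CRL-to-GA
    dating formulae (Garbhini-GA1, Hadlock, Robinson-Fleming,
    McLennan-Schluter, Sahota, Verburg, INTERGROWTH-21st), a data-driven
    model-development pipeline (clinical-criteria filtering, DBSCAN
    outlier removal, truncation supplementation, fractional-polynomial
    regression, Boruta and GLM feature selection), and a method-comparison
    suite (Bland-Altman agreement, preterm-birth rates with confidence
    intervals, Fisher tests, Jaccard classification agreement). Includes a
    synthetic cohort generator emulating LMP recall error and CRL
    measurement noise so every pipeline stage is testable without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    truncnorm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
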