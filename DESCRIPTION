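Package: ldmr
Title: Two-Sample Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization when the genetic
    instruments are in linkage disequilibrium. Reads and harmonizes GWAS
    summary statistics and signed LD correlation matrices, applies
    variant-validity filters (minor allele frequency, call rate,
    Hardy-Weinberg equilibrium, imputation info score, confounder
    association screening), selects instruments by greedy p-value ranked
    r-squared pruning or a fixed conditional-score list, and estimates the
    causal effect by generalized inverse-variance weighted regression with
    a full between-variant weight covariance, with principal-components
    stabilization for near-singular weight matrices. Includes odds-ratio
    reporting with Bonferroni-style multiple-testing flags, fixed-effect
    combination of cohort estimates, analytic power calculations, and a
    synthetic summary-statistics generator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
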