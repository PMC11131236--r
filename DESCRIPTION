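Package: metabomr
Title: Metabolome-Wide Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for metabolome-wide two-sample Mendelian
    randomization (MR) screens of circulating metabolites against downstream
    outcomes such as reproductive-timing traits. Implements instrument selection
    (genome-wide significance filtering, LD clumping, variance-explained and
    F-statistic strength checks), summary-statistic harmonization with proxy
    substitution, causal estimators (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median, weighted mode, multivariable IVW), sensitivity
    diagnostics (Cochran's Q, a residual-sum-of-squares pleiotropy outlier test,
    Steiger directionality filtering, bidirectional MR), approximate-Bayes-factor
    colocalization, hypergeometric over-representation analysis, observational
    validation regressions, and seeded synthetic-data generators emulating the
    statistical structure of GWAS summary statistics, LD reference panels and
    birth-cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
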