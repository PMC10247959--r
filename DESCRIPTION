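Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: reading and validating association tables, selecting
    independent strong instruments (significance filtering, greedy LD
    clumping, F-statistic screening, outcome-overlap exclusion), harmonizing
    exposure and outcome effects onto a shared effect allele with palindromic
    and incompatible-allele handling, and estimating causal effects with the
    inverse-variance-weighted, weighted-median, Wald-ratio and MR-Egger
    estimators plus Cochran's Q, radial outlier detection and leave-one-out
    sensitivity analyses. Includes a synthetic two-sample GWAS generator with
    known causal truth for calibration studies, and a batch driver that
    renders forest-style report tables with Bonferroni significance tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
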