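Package: cismr
Title: Cis-eQTL Mendelian Randomization with Pairwise Conditional Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-statistics pipeline for prioritizing disease genes from
    cis-eQTL instruments: instrument selection (genome-wide significance,
    LD clumping, F-statistic and Steiger screening), Wald-ratio and
    fixed-effect inverse-variance-weighted Mendelian randomization with
    Cochran's Q heterogeneity, Wakefield approximate-Bayes-factor
    colocalization, approximate conditional analysis from marginal GWAS
    statistics and a reference LD panel (COJO-style), pairwise conditional
    colocalization (PWCoCo), region-based horizontal-pleiotropy and novelty
    assessment, phenome-wide colocalization scans, and fixed-effect GWAS
    meta-analysis for replication. Includes an LD-structured synthetic-data
    generator so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
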