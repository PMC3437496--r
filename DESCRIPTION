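Package: rfigwas
Title: Feed-Efficiency GWAS Pipeline with Genomic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of feed-efficiency traits
    in beef cattle populations: derivation of residual feed intake (RFI) as
    within-feeding-group regression residuals, construction of pedigree and
    genomic relationship matrices (allele-sharing calibrated to the numerator
    relationship matrix, or VanRaden scaling), EM-REML animal models returning
    breeding values and accuracies, accuracy-weighted single-SNP association
    scans with permutation-derived genome-wide thresholds, chromosome-wise
    forward selection of QTL-tagging SNPs, two-model GBLUP estimation of the
    additive variance explained by a SNP panel, and QTL-region concordance
    analysis. A seeded synthetic-population generator emulating a half-sib
    steer design makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
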