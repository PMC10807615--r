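Package: mrkit
Title: Two-Sample Mendelian Randomisation for Summary-Level GWAS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) with GWAS
    summary statistics: reading, validating and harmonising per-SNP
    association tables onto a common effect-allele orientation; selecting
    genome-wide-significant, LD-independent instruments with strength
    diagnostics; inverse-variance-weighted, MR-Egger, weighted-median and
    MR-PRESSO causal estimators with Cochran's Q heterogeneity statistics;
    multivariable MR with conditional F-statistics; fixed-effect subgroup
    meta-analysis; a priori power and minimum-detectable-odds-ratio
    calculations for binary outcomes; and a summary-level simulator with
    known causal structure for calibration and recovery studies. All
    user-facing functions take data frames and return tibbles, with
    broom-style tidiers and ggplot2 diagnostics.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
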