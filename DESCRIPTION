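Package: ironmr
Title: Two-Sample Mendelian Randomization of Iron Status on ALS Risk
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics, built around the published instrument set linking four
    biomarkers of systemic iron status (serum iron, log ferritin, transferrin
    saturation, transferrin) to amyotrophic lateral sclerosis risk.
    Implements instrument selection (genome-wide significance, LD pruning,
    four-biomarker concordance), instrument-strength statistics (R-squared
    and F), allele harmonization with palindrome resolution,
    inverse-variance-weighted, MR-Egger and weighted-median estimators,
    the MR-PRESSO global and outlier tests, leave-one-out and single-SNP
    diagnostics, a-priori power calculations for binary outcomes, and a
    synthetic summary-statistics generator for calibration studies. All
    user-facing functions take and return data frames so analyses compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
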