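Package: mexscreen
Title: Pan-Cancer Splicing-Factor Silencing Screens and Microexon
    Inclusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening splicing factors for consistent
    tumor-versus-normal silencing across tissues, and for quantifying the
    downstream consequences on microexon inclusion. Implements per-tissue
    Wilcoxon-Mann-Whitney differential testing of expression and promoter
    methylation with Benjamini-Hochberg correction, cross-tissue
    consistency scoring, coverage-filtered differential exon inclusion
    (PSI) calling, splicing-factor-to-target-exon coupling with
    randomization-test backgrounds, mitotic-index signature scoring,
    perturbation-response target definition, and a seeded synthetic
    multi-omic cohort generator with known ground truth for end-to-end
    validation. Readers are provided for tab-separated omics matrices and
    vast-tools style inclusion tables.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
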