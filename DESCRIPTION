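Package: wntscreen
Title: Dual-Luciferase siRNA Screen Analysis and Multi-Evidence Candidate
    Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-scale dual-luciferase
    RNA-interference reporter screens: plate-matched Renilla normalization and
    percent-of-control summarization of siRNA pools, fold-change/p-value hit
    calling with gene-level consensus across redundant pools, harmonization and
    three-set Venn integration of screen hits with phosphoproteomic and
    disease-associated gene lists, AP-MS spectral-count background subtraction
    with SIF network export, and the standard validation-assay quantifications
    (reporter fold activation with t-tests, delta-delta-Ct relative expression,
    TUNEL percent-positive, densitometry percent-of-maximum). Ships seeded
    synthetic-data generators with planted ground truth so the entire analysis
    can be exercised and validated offline.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
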