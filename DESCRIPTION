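Package: peepbarcode
Title: Personalized Perturbation Profiles and Combinatorial Expression
    Barcodes for Responder Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies donor cohorts into High, Average and Low responders by
    the mean +/- 1 SD rule on a functional readout (anti-IgE-induced histamine
    release from cultured mast cells), normalizes qPCR quantities to Log2
    expression levels with plate-to-plate normalization factors and GAPDH
    referencing, builds personalized perturbation profiles (PEEP) that call
    each gene Up, Norm or Down against the combined Average+Low control range,
    and integrates per-gene calls over a signature panel into combinatorial
    "barcode" patterns and categories. Includes a seeded synthetic-cohort
    generator that emits raw plate data inverting the normalization equation,
    a simplified fold-change/p-value marker screen, and an end-to-end pipeline
    with tabular I/O.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
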