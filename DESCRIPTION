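Package: slicscreen
Title: Analysis of Pooled shRNA Dropout Screens for Drug Synthetic Lethality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for pooled short-hairpin RNA (shRNA)
    dropout screens that identify genes whose knockdown sensitizes cells to a
    drug (synthetic-lethal modifier screens). Covers read preprocessing and
    hairpin counting from FASTQ, per-hairpin differential representation
    between treatment and vehicle arms via a conditional negative-binomial
    exact test with common-dispersion estimation, direction-consistency and
    annotation filters, Benjamini-Hochberg false discovery control,
    hairpin-to-gene collapse by weighted Z-transformation (Stouffer) with
    E-values, per-screen hit calling and cross-screen intersection into
    common synthetic-lethal hits. Includes a fully parameterised screen
    simulator with planted ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
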