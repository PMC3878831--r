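Package: detoxdiv
Title: Detoxification Gene Diversity and Expression Across Insect Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalogues detoxification and stress-response genes in de novo
    insect transcriptomes from BLAST-style tabular hits. Selects significant
    best hits at an E-value threshold, removes contigs whose best match is
    bacterial, plant or fungal, classifies the remainder into detoxification
    categories and enzyme families with a keyword ontology, collapses contigs
    that match the same reference gene into inferred genes with a half-length
    rule, tabulates gene diversity per life stage, and computes RPKM-style
    normalized expression per gene, family or category. Includes a seeded
    synthetic-data generator (reference genes, fragmented contigs, hit tables,
    negative-binomial stage read counts) so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
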