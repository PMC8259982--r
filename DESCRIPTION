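Package: tadpose
Title: Position-Effect Analysis of Chromosome 22q13 Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting and validating position effects of
    chromosome 22q13 deletions in Phelan-McDermid syndrome. Implements
    interval arithmetic for deletions, genes, topologically associating
    domains (TADs) and regulatory contacts; candidate-gene prediction and
    ranking from flanking windows, TAD disruption, contact disruption,
    haploinsufficiency scores and phenotype overlap; a 2^-ddCt qPCR
    relative-expression pipeline with threshold classification; Biolog
    PM-M phenotype-microarray processing with per-well Mann-Whitney tests
    against a control panel; and seeded synthetic-data generators that
    emulate every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
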