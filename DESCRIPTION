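Package: polymorphome
Title: Transcriptome Annotation and Color-Morph Expression Analysis for
    Non-Model Arthropods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of de novo assembled transcriptomes from
    color-polymorphic spiders and similar non-model arthropods: assembly
    summary statistics, hexamer Markov-model coding-potential classification
    of open reading frames, MEGAN-style lowest-common-ancestor filtering of
    contaminant ("meta-transcriptome") contigs, reciprocal-best-hit detection
    of pigment-pathway gene homologues, housekeeping-gene-anchored
    negative-binomial differential expression between color morphs, Markov
    clustering of gene families and Dollo-parsimony reconstruction of family
    gains and losses on a species tree.  A seeded synthetic-data generator
    produces inputs with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
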