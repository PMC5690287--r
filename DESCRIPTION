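Package: stagecourse
Title: Analysis of a Whole-Embryo Developmental RNA-Seq Time Course
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing an 18-stage, replicated whole-embryo
    RNA-seq time course of zebrafish development: TPM normalisation and
    detectability, sample-space principal component analysis with per-gene
    contributions, Pearson correlation-graph construction and Markov
    Cluster Algorithm (MCL) partitioning, per-cluster chromosome
    over-representation tests, sliding-window detection of chromosomal
    co-expression domains, paralogue expression-divergence summaries, and
    rule-based filter cascades for assembled pri-miRNA transcripts and
    3'-end (polyadenylation-site) regions. A seeded synthetic-data
    generator plants temporal archetypes, chromosomal co-expression
    blocks, paralogue pairs and genome/annotation fixtures with known
    ground truth so that every stage of the pipeline can be exercised and
    validated end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
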