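Package: salivalink
Title: Whole-Ecosystem Saliva Metagenome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-ecosystem (host plus microbiota)
    shotgun sequencing of saliva. Partitions paired reads into host- and
    microbiota-originating sets by a mapping-quality rule, builds per-sample
    functional abundance profiles over a four-level subsystem hierarchy with
    core/pan function sets, enrichment signatures and ordination, links gene
    functions to their originating genomes to quantify functional redundancy
    and genome dominance, and derives consensus host SNPs by intersecting two
    caller outputs with depth filtering, genomic-region and coding-effect
    classification. Includes a synthetic-data generator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    withr,
    jsonlite,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Rsamtools,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
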