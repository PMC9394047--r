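Package: orthoconserve
Title: Cross-Species Transcriptome Conservation and GWAS Signal Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conservation of gene expression between two species
    over one-to-one orthologs: tissue-level expression summaries and
    expressed-gene counts, tissue-specificity (tau index, one-vs-rest
    differential expression), between-species differential expression and
    differential variability (F-test), co-expression conservation via the
    correlation-of-correlations (corCor) statistic and weighted-network soft
    connectivity, decile-window ranking with conserved/diverged gene-set
    partitioning, gene-set GWAS signal enrichment through a cyclical
    genotype-permutation null on summed squared marker effects, and
    chromatin-state enrichment folds around transcription start sites. A
    seeded synthetic-data generator produces paired two-species expression
    matrices, marker tables and chromatin segmentations with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
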