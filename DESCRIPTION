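Package: crypticflow
Title: Cryptic Splicing, CLIP Enrichment and Signature Scoring for
    TDP-43 Proteinopathy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for models of TDP-43
    proteinopathy. Computes junction-level percent-spliced-in (PSI) from
    splice-junction count tables, calls cryptic splicing events against a
    GTF annotation, pairs cryptic junctions into cryptic exons and
    predicts their protein-level consequence (truncation, cryptic
    peptide, nonsense-mediated-decay candidacy); implements eCLIP-style
    IP-versus-input peak enrichment statistics with a Yates chi-square /
    Fisher exact switchover and an annotation priority hierarchy;
    applies single-cell quality-control filters, threshold-based
    differential-expression presets, gene-signature scoring and
    two-axis quadrant overlap analysis. Ships seeded synthetic-data
    generators for every input so the whole pipeline can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'annotation.R'
    'clip.R'
    'consequence.R'
    'cryptic.R'
    'expression.R'
    'junction-io.R'
    'pipeline.R'
    'psi.R'
    'simulate.R'
    'toy-genome.R'
    'utils.R'
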