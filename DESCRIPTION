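Package: edicall
Title: Detection and Quantification of A-to-I RNA Editing from RNA-seq Pileups
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting and quantifying A-to-I RNA editing from
    multi-strain RNA-seq pileup data. Implements quantification of catalogued
    editing sites with editing-null-strain blacklisting, a five-criterion
    de-novo site caller with genomic-variant and mutant-change subtraction and
    replicate consolidation, strand-aware gene-region annotation, nucleotide
    context probability profiles with pseudocounts, minimum-free-energy window
    analysis of site surroundings, editing-class expression statistics, and a
    seeded synthetic pileup generator emulating a three-strain, two-stage,
    three-replicate study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, Sequencing, Coverage
RoxygenNote: 7.3.3
Collate: 
    'edicall-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'gene-models.R'
    'annotate.R'
    'context.R'
    'formats-pileup.R'
    'known-sites.R'
    'denovo.R'
    'expression.R'
    'formats-tables.R'
    'structure.R'
    'synthio.R'
    'pipeline.R'
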