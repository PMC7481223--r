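Package: epitrace
Title: Transgenerational Methylome Analysis and Epiallele Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis across pedigrees: quality filtering of per-CpG methylation
    count matrices, discovery of differentially methylated regions (DMRs)
    by recursive segmentation with empirical-Bayes moderated re-evaluation
    of logit-transformed interval means, cross-generation evaluation and
    epiallele history classification of DMRs, genomic feature annotation,
    and clutch-level phenotype statistics (thymopoietic index, clutch
    noise, transmitter classification). Includes a beta-binomial pedigree
    simulator so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
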