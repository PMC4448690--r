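Package: stresslnc
Title: Classification and Regulation Analysis of Stress-Induced Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing long noncoding RNAs
    (lncRNAs) induced by acute cellular stress. Builds transcript loci from
    merged annotations and selects representative transcripts, applies
    RPKM-based detection and differential-expression filters, classifies
    lncRNAs by position and strand relative to the nearest protein-coding
    gene (distal, overlapping, terminal-associated, promoter-associated),
    computes RNA polymerase II traveling ratios and strand-aware coverage
    metaprofiles, calls translational shifts from three-pool polysome
    fractionation arrays, and scores coding potential of transcripts via
    longest-ORF codon bias. A synthetic-data generator with planted ground
    truth allows every stage to be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Annotation, Coverage
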