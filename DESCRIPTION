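Package: caprilnc
Title: Screening and Characterisation of Long Noncoding RNAs from
    Assembled Transcriptomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate long noncoding RNAs (lncRNAs) among
    assembled transcript models by a three-scorer coding-potential
    consensus (ORF extent, adjoining-triplet hexamer bias, protein-motif
    scan), classifies candidates positionally as lincRNA, antisense or
    intronic against a reference gene annotation, tests two-group
    differential expression with a negative-binomial Wald test on FPKM
    normalised counts, predicts cis (genomic window) and trans
    (expression correlation) target genes, performs EASE-score
    functional enrichment, calls group-specific lncRNAs, and computes
    2^-ddCt qPCR fold changes. Ships a deterministic synthetic-study
    generator with planted ground truth so every stage of the pipeline
    can be validated end to end.
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
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    GeneRegulation, Annotation, Software
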