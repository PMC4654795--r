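Package: methexpress
Title: Integration of Array DNA Methylation and Gene Expression in Two-Group Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of Illumina 450K-style CpG methylation
    (beta values) and log2 microarray gene expression in two-group designs
    such as fetal versus adult tissue. Implements detection-p and sex-chromosome
    filtering, logit (M-value) transformation, per-feature linear modelling with
    empirical-Bayes variance moderation and Benjamini-Hochberg FDR, CpG-to-gene
    region mapping with promoter/first-exon (TSS/Ex1) versus UTR/gene-body
    aggregation, categorical methylation classification, contingency and
    prediction-probability statistics linking methylation change to expression
    change, control-gene-set-calibrated over-representation analysis, and a
    ground-truth synthetic data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, GeneExpression, DifferentialMethylation,
    DifferentialExpression, Microarray, MethylationArray
RoxygenNote: 7.3.3
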