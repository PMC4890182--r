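Package: fimbmeth
Title: Paired Fimbrial-Proximal DNA Methylation Reprogramming Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting excess fimbrial-versus-proximal
    DNA methylation reprogramming in paired fallopian-tube 450k beta-value
    data from BRCA1/2 mutation carriers and controls. Provides quality
    filtering and KNN imputation of beta-value matrices, empirical-Bayes
    moderated paired t-tests per CpG within each group, set-difference
    differentially methylated position (DMP) calling with median delta-beta
    thresholds, per-gene binomial enrichment, one-sided Fisher gene-set
    enrichment, annotation-matched background-resampling enrichment against
    chromatin-mark peak tracks, and top-k cross-list overlap statistics with
    odds-ratio confidence intervals. A synthetic-data generator with planted
    ground truth emulates the study design end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    fgsea,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
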