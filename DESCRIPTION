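Package: mirwin
Title: 5'-Anchored Window miRNA Quantification and Downstream Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a small-RNA sequencing analysis pipeline for isomiR-aware
    miRNA quantification and its downstream statistics: 3' adapter trimming,
    18-28 nt length filtering, perfect-match genome mapping, and abundance
    estimation anchored on a +/-3 nt window around each mature miRNA's annotated
    5' end; TMM normalization with a two-group negative-binomial exact test and
    Benjamini-Hochberg FDR for gene and miRNA count matrices; a target-gene
    log-fold-change CDF-shift (Kolmogorov-Smirnov) test of miRNA regulatory
    effect with hypergeometric set-overlap and Pearson concordance statistics;
    and biomarker/bench statistics (ROC/AUC with DeLong intervals, median-split
    Kaplan-Meier with log-rank test, 2^-ddCt relative quantification, ChIP
    percent-input, xenograft tumor volume). Ships synthetic-data generators
    (toy genomes, planted miRNA loci, isomiR-structured reads, negative-binomial
    count matrices, clinical tables) so the whole pipeline is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    stringi,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    Rsamtools,
    pROC,
    survival
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
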