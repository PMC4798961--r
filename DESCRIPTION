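Package: clipscan
Title: Scan-Statistic Peak Calling and Downstream Analysis for CLIP-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies RNA-binding-protein binding sites from CLIP-seq tag
    data using an exact scan statistic under a uniform per-gene background,
    with Bonferroni control and a cross-sample reproducibility (biological
    complexity) filter. Provides the downstream analyses typically paired
    with neuronal ELAV-like (nELAVL) CLIP studies: expression-normalized
    binding quantification and target ranking, TMM-normalized negative
    binomial differential testing of gene counts and peak heights,
    cassette-exon inclusion testing with a logit-link GLM likelihood ratio
    test, degenerate U-rich motif scanning, gene-set overlap statistics, and
    Y RNA binding and remodeling analysis. A synthetic-data generator
    reproduces the statistical structure every stage assumes, so the whole
    pipeline is testable without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, PeakDetection, AlternativeSplicing,
    DifferentialExpression, GeneRegulation, MotifDiscovery
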