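Package: BSAscan
Title: Bulked-Segregant Analysis Genome Scans with Empirical Permutation
    Thresholds
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistics and genome-scan machinery for bulked-segregant
    analysis (BSA-seq) QTL mapping from two extreme phenotype bulks. Reads
    multi-sample VCFs with per-sample allelic depths into a
    SummarizedExperiment-derived container, computes per-SNP
    SNP-index/Delta-SNP-index, the G statistic and the fourth-power Euclidean
    distance (ED4), smooths them with a tricube kernel (G') and 1 Mb/100 kb
    sliding windows, derives empirical genome-wide significance thresholds by
    Monte-Carlo permutation of bulk labels, and calls candidate QTL
    intervals. Also includes chi-square goodness-of-fit tests of Mendelian
    duplicate-gene segregation ratios and a recombinant-inbred-line bulk
    sequencing simulator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    Matrix,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, VariantAnnotation, Sequencing, QualityControl
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'BSAscan-package.R'
    'BulkSnpSet-methods.R'
    'bsa-stats.R'
    'genome-scan.R'
    'simulate.R'
    'segregation.R'
    'variant-io.R'
    'pipeline.R'
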