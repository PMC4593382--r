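Package: desire
Title: Sequencing-Depth Subsampling and Saturation Analysis for RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements DESIRE (Depth of Sequencing Iterative Reduction
    Estimator), a reproducible m-out-of-n bootstrap on aligned RNA-seq
    reads: fractions of aligned fragments are drawn without replacement,
    R times per depth, to simulate sequencing experiments at reduced
    depth. Includes gene-level fragment counting against a GTF/SAF
    annotation, CPM/RPKM normalization, the direct count-matrix scaling
    contrast, expressed-gene saturation curves with Gompertz growth-rate
    fitting, optimal sequencing-depth estimation, and comparison of
    expression-distribution moments (mean, variance, skewness, kurtosis)
    between phenotype groups. A synthetic-data generator produces
    annotations and aligned reads with known ground truth so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    data.table,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Rsamtools,
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
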