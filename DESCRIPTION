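Package: sweepscan
Title: Multi-Statistic Selective-Sweep Scans for Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Windowed scans for signatures of positive selection in phased
    population genomic data: nucleotide diversity and log2 diversity-ratio
    scans, Weir-Cockerham F_ST, a cross-population composite-likelihood
    sweep scan, iHS haplotype statistics with frequency-bin
    standardization, a windowed polymorphism/divergence goodness-of-fit
    (HKA-style) test against a genome-average neutral background, and V_ST
    differentiation on copy-number intensity data; plus
    empirical-percentile thresholding, multi-statistic window
    intersection, interval merging and annotation, and a
    length-preserving permutation test for annotation overlap. Includes a
    forward Wright-Fisher simulator with hard sweeps, outgroup
    divergence, CNV intensity matrices and QTL intervals for calibration
    and power studies, LD-decay curves, and LD-based recent effective
    population size estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    pracma,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
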