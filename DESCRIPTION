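Package: epiqtl
Title: Population Analysis of Gene-Body Methylation Epialleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing natural gene-body CG methylation (gbM)
    variation in plant populations: per-site methylation calling from
    bisulfite read counts, methylome segmentation and per-accession gene
    epigenetic-state classification (UM/gbM/teM), grouped spike-and-slab
    Bayesian partitioning of expression variance among gbM, teM and SNP
    marker groups, methylation-expression association (eQTL) mapping with
    Bonferroni/FDR tiers, genetic-confound accounting (cis scans, nested
    populations, SNP-invariant haplogroups, structural-variant-invariant
    subpopulations, linkage disequilibrium, trans-QTL variance), epigenome-
    wide association with linear and mixed linear models, genomic-control
    inflation correction, and methylation-perturbation expression contrasts.
    Includes a synthetic-data generator (cooperative epimutation dynamics,
    structured genotypes, sparse-effect expression, bisulfite read counts,
    epiallele-driven traits) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
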