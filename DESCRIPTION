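Package: erosionkit
Title: Temporal Genomic Erosion Analyses for Two-Epoch Resequencing Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify genomic erosion between a historic (museum) and a
    contemporary sampling epoch from low- to medium-coverage whole-genome
    resequencing data. Implements genotype-likelihood computation from read
    pileups with an error model estimated from a haploid reference,
    ANGSD-style site filtering (minor allele frequency, SNP likelihood-ratio
    test, transversions only), folded two-class EM estimation of individual
    genome-wide heterozygosity in windows, a downsampling-based calibration of
    coverage bias with polynomial correction, PLINK-style runs-of-homozygosity
    calling with FROH inbreeding coefficients and length-class age mapping,
    mitochondrial haplotype collapsing with haplotype diversity, a permutation
    test for diversity loss, median-joining haplotype networks, and
    genotype-likelihood population structure (covariance PCA and admixture
    EM). A synthetic-data generator with known ground truth (two epochs, a
    bottleneck, sequencing error, post-mortem damage, planted autozygous
    tracts, epoch-specific mitochondrial haplotype frequencies) makes every
    stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
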