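Package: mbmixcheck
Title: Sample Mix-Up and Mixture Detection for Shotgun Metagenome Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Verifies sample identity in shotgun-metagenome studies that
    include host genotype data. Host-derived sequence reads overlapping
    biallelic SNPs are tabulated against the SNP genotypes of each genomic
    DNA sample; a genotype-discordance distance identifies sample swaps,
    and a two-parameter binomial mixture model (contaminant proportion p,
    sequencing error rate epsilon) fitted by maximum likelihood, with a
    likelihood ratio test against no contamination, identifies and
    quantifies mixtures of two samples. Includes genotype preparation
    from multi-founder diplotype probabilities, a synthetic-cohort
    simulator, and an end-to-end study report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicRanges,
    vcfR,
    optparse
Config/testthat/edition: 3
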