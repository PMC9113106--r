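Package: bottleneckR
Title: Conservation Genomics of Bottlenecked Populations: Demography,
    Diversity, Inbreeding and Mutational Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for assessing the genomic consequences of a
    recent population bottleneck from diploid genotype data: a forward-in-time
    Wright-Fisher simulator with demographic events and two-deme migration;
    folded site-frequency-spectrum extraction and demographic scenario ranking
    by multinomial log-likelihood; genome-wide diversity statistics
    (heterozygosity, nucleotide diversity, Watterson's theta, Tajima's D,
    excess-homozygosity inbreeding F_H); window-based detection of runs of
    homozygosity with length-binned F_ROH inbreeding profiles; codon-level
    classification of single-nucleotide variants into synonymous, missense and
    loss-of-function categories with per-individual mutational-load summaries;
    allele-sharing distances and principal coordinate analysis; and synthetic
    data generators with known truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
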