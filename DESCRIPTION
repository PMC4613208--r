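Package: xsweep
Title: Selection-Signature Scans on a Single Chromosome with iHS and FST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of recent positive selection on a single
    chromosome from phased SNP-chip genotypes, combining a within-population
    scan based on the integrated haplotype score (iHS, from extended
    haplotype homozygosity) with a between-population scan based on per-SNP
    FST from expected heterozygosities. Includes PLINK-style quality control
    (call rate, minor allele frequency, Hardy-Weinberg exact test,
    duplicate detection), boxplot and threshold outlier calling, candidate
    region construction with interval merging and overlap accounting, gene
    annotation against user-supplied gene models, and a seeded
    haplotype simulator (Balding-Nichols differentiation, founder-mosaic
    linkage, injected hard sweeps) that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
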