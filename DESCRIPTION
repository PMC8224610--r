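Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from SNP
    Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and interpretation of runs of homozygosity (ROH) in
    diploid SNP-array genotypes, aimed at livestock conservation genetics.
    Reads PED/MAP genotype files, applies marker and sample quality control,
    calls ROH per individual with an exhaustive run-based scanner (or a
    sliding-window emulation of PLINK's --homozyg), computes the genomic
    inbreeding coefficient F_ROH and length-class decompositions, scans the
    pooled meta-population for ROH islands with gene annotation, and embeds
    individuals by classical multidimensional scaling of identity-by-state
    distances. A genotype simulator with planted autozygous segments
    provides ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
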