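Package: allelepanel
Title: Full-Length Allele Reference Panels from Multiplexed Long-Read
    Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs full-length, quality-refined allele reference
    panels for multi-gene loci (modeled on HLA class I) from multiplexed
    long-read amplicon sequencing plus per-sample short-read data.
    Long reads are separated by primer set and sample before assembly,
    clustered into haplotype groups and polished into draft consensus
    alleles; variant positions identified by multiple sequence alignment
    are validated and corrected against each carrier's short reads; a
    diploid genotype likelihood filter with copy-number awareness selects
    the final panel, which is then characterized against a known-allele
    database (closest subtypes, 4/6/8-digit novelty classes, reference
    extension and population coverage). A synthetic-data generator
    emulating nested co-amplification, a deletable locus and
    indel-dominated long-read errors makes every stage testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
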