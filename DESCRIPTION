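Package: ltrmapr
Title: Genome-Wide Mapping of HERV-K (HML-2) Integration Sites from
    LTR-Targeted Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for locating human endogenous retrovirus K (HML-2)
    proviral and solo-LTR integration sites from PCR-based LTR-targeted
    enrichment sequencing libraries. Implements the full bioinformatic
    workflow: catalog management for known integration loci, quality
    trimming, duplicate removal and read-pair merging, detection of
    LTR-host chimeric reads by terminal-bait matching, linker stripping
    and removal of retrovirus-internal amplicons, unique mapping of host
    flanks with a seeded ungapped aligner (or import of external SAM
    alignments), per-locus detection and counts-per-million
    quantification with novel-locus discovery via junction clustering
    and target-site-duplication classification, and calling of
    insertionally polymorphic loci between individuals with a
    conditional-binomial exact test combined with a CPM fold-change
    rule. A protocol simulator generates synthetic diploid genomes,
    genotypes and paired-end enrichment reads with full ground truth so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
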