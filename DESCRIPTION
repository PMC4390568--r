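Package: hapsweep
Title: Haplotype-Based Selective Sweep Detection in Divergently Selected Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps between divergently selected lines from
    dense SNP genotypes using a haplotype-cluster differentiation statistic
    (hapFLK): Reynolds-distance kinship estimation, a fastPHASE-style
    haplotype-cluster hidden Markov model fitted by EM on unphased genotypes
    (crossbred F1 individuals included to enlarge the sample), a robust
    scaled-chi-square null with Storey q-values, sweep-region calling with
    QTL colocalization and coverage enrichment, lightweight coding-consequence
    annotation, and a cis-regulation evidence layer (allele-specific
    expression ratios and delta-Ct differential expression). A forward-in-time
    simulator of the divergent-line breeding design generates genotypes and
    expression fixtures so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    vcfR,
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
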