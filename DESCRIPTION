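Package: dupdiverge
Title: Sequence, Structural and Expression Divergence of Duplicate Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identify duplicate gene pairs in a genome from all-vs-all protein
    alignments by reciprocal best hits under coverage and length-dependent
    identity criteria, estimate synonymous and nonsynonymous divergence (dS, dN)
    by Nei-Gojobori counting with Jukes-Cantor correction on protein-guided
    codon alignments, classify exon-intron structural divergence of each pair,
    quantify tissue-expression divergence from an FPKM matrix, and link the
    three divergence axes statistically (rank tests, binned regressions, and
    analysis of covariance controlling for synonymous divergence). A simulator
    generates gene families, genomes and expression matrices with the
    statistical structure the analyses assume, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
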