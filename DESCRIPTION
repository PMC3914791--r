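Package: rgatools
Title: Cataloguing and Evolutionary Analysis of NBS-Domain Resistance Gene
    Analogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies resistance gene analogues (RGAs)
    carrying a nucleotide-binding site (NB-ARC) domain from gene models,
    protein/CDS sequences and precomputed domain-hit tables. Collapses
    putative alleles by overlap and protein similarity, calls positional
    RGA clusters on chromosomes, and summarises genome organization.
    Builds bootstrapped neighbor-joining phylogenies of NBS domains with
    Dayhoff maximum-likelihood distances and majority-rule consensus,
    extracts genus-specific clades, estimates pairwise synonymous
    divergence (Ks) with the Nei-Gojobori (1986) counting method, and
    detects duplicated-chromosome connections from low-Ks gene pairs.
    Includes a fully seeded synthetic genome generator with ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
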