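Package: retinawalk
Title: Targeted Transcript Assembly and RNAi Knockdown Quantitation for
    Insect Retina Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed toolkit for the computational
    chain used in targeted studies of insect phototransduction genes: quality
    grooming of short paired reads, low-stringency BLOSUM seed search,
    greedy overlap-consensus transcriptome walking to full coding sequences,
    read-count relative abundance estimation under an identical-nucleotide
    criterion, efficiency-corrected comparative-Cq (delta-delta-Cq) qPCR
    quantitation with multi-reference normalization, and nonparametric
    Mann-Whitney analysis of electroretinogram attenuation time courses.
    Includes a ground-truthed synthetic-data generator emulating a nocturnal
    insect retina (two green-opsin paralogs, a UV opsin, TRP and TRPL channel
    homologs, reference genes), RNAi knockdown scenarios, qPCR plates and ERG
    cohorts, so every estimator can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
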