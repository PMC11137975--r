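Package: ncpred
Title: Plant Non-Coding RNA Discrimination by Fusing Handcrafted and Recurrent Deep Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies plant transcripts as non-coding RNA (ncRNA) or
    messenger RNA (mRNA) by fusing 91 handcrafted sequence features
    (mono-, di- and tri-nucleotide frequencies, open-reading-frame
    derived scores and coordinates, length and GC content) with a
    1200-dimensional deep feature vector extracted from a gated
    recurrent unit (GRU) network trained on embedded nucleotide
    sequences, and training a random forest on the fused
    representation. Includes variance-threshold and ANOVA F-test
    feature-selection pathways, stratified dataset splitting, the
    standard seven confusion-matrix metrics plus ROC/AUC, a paired
    z-test on discordant ncRNA classifications for comparing
    classifiers, and a seeded synthetic transcript generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
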