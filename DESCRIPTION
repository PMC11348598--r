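Package: polswap
Title: Detecting DNA Polymerase Gene Swapping in Tailed Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome comparative pipeline for discovering DNA polymerase
    (DNAP) gene swapping among tailed bacteriophages. Extracts open reading
    frames from phage genomes, computes reciprocal-best-hit proteome coverage
    distances between genome pairs, builds a neighbor-joining genome tree,
    ultrametrizes it by iterative subtree balancing, cuts it into fixed-depth
    clades, classifies DNAP genes into families (PolA/PolB/PolC) by best-hit
    search against labeled references, and detects and counts within-clade
    DNAP family replacements by small parsimony. Includes a phage-genome
    simulator with planted swap events for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
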