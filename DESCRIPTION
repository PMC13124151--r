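Package: gcfitness
Title: Simulation-Based Inference of the Affinity-Fitness Response in Germinal Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to learn the affinity-fitness response function of germinal
    center B cells from collections of phylogenetic trees. Provides a cell-based
    forward birth-death-mutation simulator with a sigmoid affinity-fitness
    response and a logistic carrying-capacity constraint, synthetic
    deep-mutational-scan and 5-mer somatic-hypermutation fixtures, an
    affinity-augmented compact bijective ladderized vector (CBLV) tree encoding,
    a convolutional inference network trained with a curve-difference loss, and
    a two-step procedure combining conditional neural inference with
    summary-statistic matching over non-sigmoid parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    tibble,
    dplyr,
    rlang,
    tidyr,
    generics,
    ggplot2,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
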