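Package: coexland
Title: Gene-Pair Coexpression Landscapes from Stochastic Two-Gene Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes single-cell gene-pair coexpression landscapes from
    discrete stochastic two-gene regulatory network models by exact
    steady-state solution of the chemical master equation, characterizes
    landscape shape with a PCA shape-space trained on libraries of model
    landscapes, and projects empirical gene-pair landscapes estimated from
    annotated single-cell RNA-seq count tables into that space to derive
    and cluster developmental landscape-shape trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    parallel,
    readr,
    generics,
    ggplot2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
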