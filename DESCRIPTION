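Package: muxrec
Title: Reconstruction of Partially Observed Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the complete topology of sparse, undirected, unweighted
    multiplex networks from partially observed layers. Implements an
    Expectation-Maximization-Aggregation (EMA) solver that couples a
    configuration-model link probability with an interlayer OR-aggregation
    Bayes update, alongside the plain EM solver and a uniform random
    baseline. Includes a node-masking observation model, imbalanced
    classification metrics (Matthews correlation coefficient, G-mean), a
    synthetic multiplex generator with a tunable interlayer edge overlap,
    per-layer descriptive statistics, experiment sweep drivers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
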