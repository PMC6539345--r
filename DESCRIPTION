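Package: siloxqsrr
Title: QSRR Characterisation of Poly(Siloxane) GC Stationary Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) modelling of
    the first five McReynolds constants (X, Y, Z, U, S) of 29 poly(siloxane)
    gas-chromatographic stationary phases. Provides the phase composition and
    McReynolds tables, a 20-unit oligomer graph builder for the phases with
    graph-computable descriptors (rotatable-bond count, N-Si atom-pair
    presence), descriptor pre-filtering (variance and correlation), ordinary
    least-squares QSRR fitting with leave-one-out cross-validation, genetic
    algorithm descriptor selection with multi-start pooling, external-set and
    Monte Carlo validation statistics, PCA-based column classification with
    biplot export, and a seeded synthetic QSRR data generator for testing the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Open Babel (obabel, used only by the SMILES round-trip
    tests)
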