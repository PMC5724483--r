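Package: codemo
Title: Hierarchical Co-Demographic Simulation and Inference for
    Comparative Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-taxa reference tables under hierarchical
    co-demographic models in which independent populations share
    instantaneous size-change pulses, summarises them as the aggregate
    site frequency spectrum or multi-taxa mitochondrial statistics, and
    infers the hyperparameters governing synchrony (pulse counts and
    taxon-assignment proportions) by hierarchical ABC rejection and
    hierarchical random-forest regression.  Includes a fast coalescent
    engine for folded site frequency spectra from independent
    genealogies, pulse-buffered prior distributions on event times, and
    leave-one-out cross-validation machinery scored by Pearson's r and
    RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
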