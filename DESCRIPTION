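Package: dscfit
Title: Global Fitting of Protein Unfolding Models to DSC Scans with Reheating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and globally fits differential scanning calorimetry (DSC)
    thermograms of protein unfolding, treating first scans, cooling, and reheated
    scans as one experiment governed by one model. Implements the four standard
    single-peak transition models (reversible two-state, irreversible two-state,
    Lumry-Eyring with fast first-step equilibrium, and the general three-state
    model with explicit forward and reverse rate constants) plus chained
    extensions with appended irreversible steps, propagating native-state decay
    factors through arbitrary heat/cool/reheat temperature programs. Provides
    residual-based diagnostics for alternative refolding pathways, reversibility
    classification from reheats, and planning of informative reheat terminal
    temperatures, together with seeded synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
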