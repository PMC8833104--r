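Package: tcrfluct
Title: Stochastic Fluctuations in TCR-pMHC Binding Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stationary distributions and information-theoretic
    summaries (Shannon entropy, entropy rate, variance rate, adhesion
    probability) for reversible T cell receptor (TCR) and peptide-MHC
    (pMHC) binding within a cell-cell contact area, together with an
    exact Gillespie stochastic simulator of a minimal five-reaction T
    cell signalling model combining serial engagement, reversible TCR
    conformational change and TCR aggregation. Includes a mean-field
    (mass-action ODE) cross-check, dose-response sweep machinery for
    locating optimal ligand doses and 2D affinities, unit conversions
    from measured surface densities and effective 2D affinities to
    copy-number parameters, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
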