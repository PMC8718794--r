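Package: alternans
Title: Troponin Calcium Kinetics, Calcium-Release-Unit Alternans
    Simulation, and Cardiac Transient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how slowed calcium unbinding from cardiac
    troponin promotes calcium alternans.  Includes a stochastic
    three-dimensional lattice model of coupled calcium release units with
    explicit troponin buffering and pacing protocols; per-beat action
    potential and calcium transient metrics (APD/CaTD at arbitrary
    recovery fractions, triangulation, alternans and entrainment
    classification) from dual-channel fluorescence traces; Hill-equation
    calcium sensitivity (Kd) and stopped-flow single-exponential
    dissociation rate (koff) fitting; housekeeping-normalised transcript
    count analysis with Welch tests and Benjamini-Yekutieli false
    discovery rate control plus delta-delta-Ct quantification; and seeded
    synthetic-data generators that emulate each assay for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
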