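Package: oxtrsig
Title: Kinetic Modeling and Trace Analysis of OXTR A218T Calcium Signaling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the functional consequences of the oxytocin
    receptor (OXTR) A218T variant in silico. Provides an ODE model of
    oxytocin-stimulated, Gq-mediated calcium release from the endoplasmic
    reticulum in which wild type and variant differ in a single
    receptor/G-protein coupling rate constant; quantitative summary metrics
    for measured or simulated calcium transients (baseline, amplitude, area
    under the curve, full width at half maximum); single-parameter
    calibration of the variant coupling constant; cross-referencing of
    differential-expression tables against SFARI-style autism gene lists
    with Benjamini-Hochberg filtering; and geometric contact-environment
    analysis of the variant site in monomeric and dimeric receptor
    coordinates. Includes generators for synthetic calcium traces,
    expression tables and idealized helix coordinate files used throughout
    the test suite.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
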