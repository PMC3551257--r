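Package: hepasim
Title: Multi-Scale Simulation of Acetaminophen Hepatotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale simulator of acetaminophen (APAP) pharmacokinetics and
    hepatotoxicity. A kinetic hepatocyte model of APAP metabolism (CYP-mediated
    NAPQI formation, phase II conjugation, glutathione turnover and
    ROS/H2O2-driven necrosis) is embedded in a zonated liver-lobule model with
    dispersive sinusoidal transport and coupled to a flow-limited whole-body
    PBPK model. Includes in-vitro LC50 calibration of the injury threshold,
    oral dose scans, CYP-variant scans, and a well-stirred reference liver for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
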