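Package: radbreak
Title: Desk-Scale Simulation of Radiation-Induced DNA Damage and Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the induction, classification and repair of
    radiation-induced DNA strand breaks in a human fibroblast cell nucleus
    at desk scale. Provides a fractal (Hilbert-curve) full-genome chromatin
    geometry inside an ellipsoidal nucleus, a parametric track fixture that
    emulates energy depositions and water-radiolysis species for particles
    of a given linear energy transfer, an independent-reaction-time (IRT)
    chemistry engine with a radical kill distance, direct and hydroxyl-radical
    mediated strand-break scoring with SSB/DSB complexity classification, a
    double-strand-break repair kinetics model producing gamma-H2AX foci
    curves, and readers/writers for configuration, event and Standard DNA
    Damage (SDD) files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
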