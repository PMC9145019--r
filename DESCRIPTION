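Package: clopbpk
Title: Parent-Metabolite PBPK Modeling of Clopidogrel with CYP2C19
    Phenotypes and Drug Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reduced whole-body physiologically based pharmacokinetic
    (PBPK) simulator for clopidogrel and its four relevant metabolites
    (clopidogrel carboxylic acid, clopidogrel acyl glucuronide,
    2-oxo-clopidogrel, and the active thiol metabolite). Implements
    Michaelis-Menten parent-metabolite kinetics with CES1/CES2, UGT2B7,
    CYP2C19 and CYP3A4, CYP2C19 phenotype (activity score) scaling,
    enzyme turnover with competitive inhibition, mechanism-based
    inactivation and induction, dose-event simulation via a compiled
    adaptive Runge-Kutta integrator, noncompartmental PK metrics,
    log-scale model evaluation statistics (MRD, GMFE, 2-fold
    goodness-of-fit, Guest acceptance limits), Levenberg-Marquardt
    parameter fitting with the stepwise parent-first strategy, simplified
    victim/perpetrator drug stubs for drug-gene and drug-drug interaction
    ratio prediction, and a synthetic study-data generator for end-to-end
    testing without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
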