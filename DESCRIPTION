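Package: neoperem
Title: Population Pharmacokinetics and Dosing Simulation of Meropenem in
    Neonatal and Pediatric ECMO/CRRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-pharmacokinetic workflow for meropenem in critically
    ill neonates and children supported by extracorporeal membrane
    oxygenation (ECMO) with or without continuous renal replacement therapy
    (CRRT). Provides the final one-compartment body-weight/CRRT covariate
    model with closed-form infusion kinetics, Monte Carlo probability of
    target attainment (fT>MIC) dosing simulations, Laplace nonlinear
    mixed-effects estimation with forward stepwise covariate modeling,
    nonparametric bootstrap, normalized prediction distribution errors and
    residual diagnostics, and a generator of synthetic sparse
    therapeutic-drug-monitoring datasets emulating the study cohort.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
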