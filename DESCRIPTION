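Package: escipk
Title: Population Pharmacokinetics of Escitalopram with CYP2C19 and Age
    Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of sparse therapeutic
    drug monitoring data for escitalopram in psychiatric patients. Fits a
    one-compartment oral model with first-order conditional estimation
    with eta-epsilon interaction (FOCE-I), supports stepwise covariate
    selection on likelihood-ratio thresholds, model validation by
    nonparametric bootstrap, conditional weighted residuals (CWRES) and
    normalized prediction distribution errors (NPDE), and steady-state
    dose-regimen simulation against the AGNP therapeutic reference range
    (15-80 ng/ml, alert 160 ng/ml) stratified by age and CYP2C19
    metabolizer phenotype. Includes a synthetic-cohort generator that
    reproduces the design of a 106-patient trough-dominated monitoring
    study for simulation-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
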