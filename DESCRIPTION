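Package: vancopk
Title: Population Pharmacokinetics and Model-Informed Dosing of Vancomycin in
    Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: One-compartment intravenous-infusion pharmacokinetic model of
    vancomycin in patients with impaired renal function, with Cockcroft-Gault
    creatinine clearance as the clearance covariate.  Provides deterministic
    concentration prediction with superposition, stochastic cohort simulation
    under log-normal inter-individual variability and a combined
    additive + proportional residual-error model, Laplace/FOCE-style
    population parameter estimation with bootstrap and conditional weighted
    residuals, MAP-Bayesian individual estimation from measured troughs,
    trough-targeted dose-regimen recommendation under clinical safety
    constraints, prediction-accuracy metrics (MAE, MSE, RMSE, PE%, MAPE%),
    Bland-Altman agreement analysis, visual predictive checks, and a
    synthetic-cohort generator so that the whole pipeline is exercisable
    without patient data.  A command-line interface exposes the simulation,
    fitting, validation and dosing tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
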