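Package: saempk
Title: Population Pharmacokinetics of Resveratrol in Rats by Stochastic
    Approximation EM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-compartment mammillary pharmacokinetic models for
    intravenous bolus and first-order oral absorption in analytic and ODE
    form, per-subject non-compartmental analysis (terminal slope, AUC/AUMC,
    clearance, bioavailability), nonlinear mixed-effects estimation by the
    stochastic approximation EM (SAEM) algorithm with log-normal
    between-subject variability and a proportional residual-error model,
    importance-sampling log-likelihood with AIC/BIC/LRT model comparison,
    and simulation-based diagnostics (visual predictive checks, normalized
    prediction distribution errors, goodness-of-fit tables). Includes
    synthetic-data generators emulating a preclinical resveratrol study in
    rats (plasma designs for both routes, terminal-sampling tissue
    distribution, ultrafiltration protein binding, calibration standards)
    and bioanalytical method-validation statistics (weighted calibration
    regression, precision/accuracy/recovery/stability checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
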