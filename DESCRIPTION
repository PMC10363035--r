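Package: tgios
Title: Tumor Growth Inhibition-Overall Survival Modeling and Trial Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-stage tumor growth inhibition (TGI) to overall survival (OS)
    modeling for oncology trials. Fits a biexponential tumor-size model to
    longitudinal sum-of-longest-diameters data as a nonlinear mixed-effects
    model (Laplace marginal likelihood via 'TMB'), extracts empirical Bayes
    estimates of the individual tumor growth rate constant KG with eta
    shrinkage diagnostics, links log(KG) and baseline prognostic factors to
    survival through a log-normal accelerated failure time model fitted by
    censored maximum likelihood, and simulates replicate virtual trials to
    obtain OS distributions, landmark survival rates, and hazard ratios with
    95% prediction intervals. Includes a synthetic-trial generator emulating
    an ALK-positive first-line NSCLC study design so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    TMB,
    stats,
    utils,
    survival,
    jsonlite
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    statmod,
    withr
Config/testthat/edition: 3
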