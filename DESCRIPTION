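Package: hfdtrial
Title: Adaptive Platform Trials with Hospital-Free-Day Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis machinery for a Bayesian adaptive
    perioperative platform trial whose primary endpoint is 90-day
    hospital-free days (HFD-90), an ordinal composite of death (-1),
    full-period hospitalisation (0) and days alive and out of hospital
    (1-90). Provides a calibrated synthetic-patient generator, endpoint
    construction from hospital-course event records, stratified
    sqrt(3):1:1:1 randomization with response-adaptive weight updates,
    a hierarchical Bayesian proportional-odds model borrowing across
    metformin doses and pre-operative treatment durations (fast Laplace
    and MCMC engines), frequentist secondary/sensitivity/subgroup
    analyses, and a whole-trial simulator for operating characteristics
    (power, type-I error, expected sample size).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    coda,
    knitr,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
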