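Package: cocer
Title: Exposure-Response Modelling of Contraceptive Efficacy via the
    Operational Model of Agonism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links dose, steady-state exposure and contraceptive efficacy
    endpoints (Pearl Index and ovulation rate) across progestins with the
    Black-Leff operational model of agonism. Provides naive-pooled,
    subject-weighted maximum-likelihood fitting with closed-form profiling
    of the residual error, Wald uncertainty, bivariate log-normal simulation
    and correlation analysis of transducer constants, a configurable
    dose-to-exposure table with virtual-population simulation, and a
    CYP3A4-induction / body-mass-index scenario engine producing predicted
    endpoints, percent changes and incidence-rate ratios. Includes a seeded
    synthetic trial-arm generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
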