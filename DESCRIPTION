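Package: qdrlart
Title: Quantum Deep Reinforcement Learning for Response-Adapted Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision-support framework for knowledge-based
    response-adapted radiotherapy. Builds a model-based artificial
    radiotherapy environment from radiobiological transition rules (gEUD,
    EQD2) and logistic tumor-control / pneumonitis outcome estimators,
    trains a double deep-Q agent whose dose selection runs on a simulated
    quantum register (fixed-depth controller circuit or Grover
    amplification, with OpenQASM 2.0 export), augments small cohorts with a
    Wasserstein GAN with gradient penalty, and scores recommendations with
    a dose-similarity metric and an outcome-based self-evaluation scheme.
    Includes a synthetic longitudinal NSCLC cohort generator for end-to-end
    experiments.
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
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
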