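Package: pupilarousal
Title: Reward-Anticipatory Pupillometry and Bayesian Evidence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and Bayesian analysis of task-evoked
    pupillometry in a reward-anticipation paradigm. Generates synthetic cohorts
    of pupil/gaze traces with configurable ground-truth effect structure,
    implements blink interpolation and run/trial quality control, scores pupil
    dilation (the first derivative of pupil size) over the anticipation window,
    computes default Bayes factors for Pearson correlations (stretched beta
    prior) and independent-samples t tests (JZS Cauchy prior), estimates
    split-half reliability, and fits a Bayesian measurement-error model that
    infers the latent correlation between pupil dilation and depressive symptom
    load via MCMC (JAGS).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    data.table,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
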