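Package: eftrial
Title: Simulation and Bayesian Analysis of School-Based Executive-Function Training Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and analysis toolkit for randomised
    controlled trials of digital executive-function training in primary-school
    children. Generates synthetic cohorts with configurable intervention
    effects, classroom clustering and missingness; simulates trial-by-trial
    behaviour on six cognitive assessment tasks (anticipated-response
    stop-signal, child flanker/attention-network, backwards digit span, Corsi
    block tapping, card sorting, dimensional change card sort) and six
    adaptive training exercises; scores task logs with the field's standard
    formulas and quality-control cut-offs, including integration-method
    stop-signal reaction time; provides trial operations (blocked
    randomisation with balance checking, noncentral-t power analysis,
    compliance classification, missingness summaries, chained-equation
    imputation); and fits Bayesian two-indicator latent change score models
    across a four-step group-invariance ladder with posterior predictive
    p-values, leave-one-out model comparison and Savage-Dickey Bayes factors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
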