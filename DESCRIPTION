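Package: clustrial
Title: Design and Analysis of Cluster Randomised Trials with Screening Funnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing two-arm cluster randomised
    trials recruited through school-based screening funnels, as used in
    targeted child-anxiety prevention research. Provides variable-cluster-size
    power and sample-size calculations, stratified blocked randomisation with
    pupil-count ordering, questionnaire scoring with prorating rules,
    a synthetic trial generator with a realistic recruitment funnel,
    multilevel joint-model multiple imputation, marginal (GEE) and mixed-model
    intention-to-treat estimation with Rubin pooling, Bayesian multilevel
    mediation, complier average causal effect estimation by two-stage residual
    inclusion with cluster bootstrap, and CONSORT-style flow reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
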