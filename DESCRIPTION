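Package: offertask
Title: Modelling Self-Control in a Sequential Offer Go/Nogo Task
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and modelling a sequential offer
    accept/reject (go/nogo) task in which early acceptance of high-value
    offers degrades the distribution of future offers, dissociating the
    immediate value of acting from its long-term value. Provides the
    task's generative engine, a belief-state dynamic-programming agent
    that computes optimal long-term values, softmax choice models that
    trade off immediate against long-term value, hierarchical
    expectation-maximization (Type-II maximum likelihood) model fitting
    with integrated-BIC model comparison and Cox-Snell pseudo-r-squared,
    descriptive acceptance-grid and robust logistic-regression analyses
    of choice, and a synthetic-data generator for parameter- and
    model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
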