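Package: smtgen
Title: Synthetic Mediator Trajectories from Ensemble-Calibrated
    Agent-Based Models of Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates labeled synthetic multidimensional molecular-mediator
    time series for machine-learning applications in acute inflammation.
    A stochastic two-dimensional agent-based model of the endothelial-blood
    interface is parameterized by a Model Rule Matrix (MRM) linking mediator
    entities to cell behavioral rules.  A genetic-algorithm plus
    active-learning pipeline identifies the ensemble of MRM configurations
    that cannot be falsified by sparse multiplexed cytokine observations,
    and the valid ensemble is run with stochastic replicates to emit dense,
    outcome-labeled synthetic trajectory spaces together with cohort
    separation and range-expansion diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
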