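Package: dsindex
Title: Disease State Index Modelling and Prodromal-AD Criteria Evaluation
Version: 0.1.0
Authors@R: person("dsindex", "maintainers", email = "dsindex@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting conversion from mild cognitive impairment
    (MCI) to Alzheimer's disease from baseline clinical, genetic, MRI and
    cerebrospinal-fluid measurements. Implements the Disease State Index
    (DSI), a missing-data-tolerant composite score in [0,1] built from
    per-feature fitness values against healthy and disease reference
    populations weighted by Youden-index relevance; the dichotomized
    research criteria for prodromal AD (hippocampal-type memory impairment,
    medial temporal atrophy rating, CSF Tau and amyloid-beta 1-42 cutoffs)
    with four-way likelihood-of-AD categorisation; diagnostic-accuracy
    statistics (exact binomial confidence intervals, McNemar's paired test,
    Cohen's kappa); and a seeded generator of synthetic ADNI-like MCI
    cohorts with exact stratum and modality-missingness counts so that the
    whole pipeline runs without any restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
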