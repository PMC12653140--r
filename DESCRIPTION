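Package: phqnet
Title: Bayesian Network Analysis of Depressive Symptom Structure by
    Metabolic Syndrome Status
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the conditional-dependence structure of
    PHQ-9 depressive symptoms between adults with and without metabolic
    syndrome. Provides a 3-of-5 metabolic-syndrome classifier with the
    AHA/IDF-style thresholds, group descriptive statistics with pooled-SD
    Cohen's d and odds ratios, score-based Bayesian-network structure
    learning (decomposable BIC, hill-climbing search, exhaustive small-graph
    oracle), nonparametric bootstrap edge-stability analysis with
    threshold-averaged networks, a synthetic cohort generator with known
    ground-truth symptom graphs, and publication-style reporting (arc and
    stability tables, DOT/GraphML export, run manifests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    optparse
Config/testthat/edition: 3
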