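Package: frnet
Title: Fast-Ripple Network Analysis for Epilepsy Surgical Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds inter-ictal fast-ripple (FR) networks from per-contact
    high-frequency-oscillation event catalogs and stereo-EEG electrode
    geometry: Euclidean distance networks, rate-distance networks, and
    mutual-information networks estimated from FR event trains with an
    adaptive inter-spike-interval partition. Computes weighted graph
    measures (radius, characteristic path length, local efficiency, nodal
    strength), mixed-effects models of event spectral features, ROC/AUC
    with bootstrap confidence intervals, PCA with rank-sum tests, and an
    RBF-kernel support-vector classifier of surgical non-responders. A
    synthetic cohort generator based on coupled Poisson point processes
    provides reproducible responder and non-responder phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    lme4,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
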