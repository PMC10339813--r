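Package: psinetfs
Title: Phase-Synchronization Brain Networks and Multi-Objective Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds EEG functional networks from band-limited multichannel
    recordings via the phase synchronization index (PSI), extracts fourteen
    graph-topology features per network, and selects discriminative feature
    subsets with a multi-objective particle swarm optimizer augmented by
    Gaussian differential mutation (MOPSO-GDM), evaluated against NSGA-II,
    plain MOPSO and MOPSO-M baselines. Includes FIR band decomposition,
    thresholded binary network construction, degree-preserving null ensembles
    for small-worldness and motif z-scores, wrapper objectives built on SVM,
    naive Bayes and discriminant analysis cross-validation error plus a
    Fisher-style distance measure, the ZDT benchmark suite with analytic
    Pareto fronts, and synthetic two-group signal and feature generators so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
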