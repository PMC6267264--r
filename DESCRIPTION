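Package: connsig
Title: Brain Networks from Task-Independent Connectivity and Their Cognitive Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives brain networks from task-independent structural
    (streamline-count) and functional (BOLD correlation) connectivity over a
    set of cortical regions of interest, and formally establishes each
    network's cognitive signature. Implements double thresholding of
    streamline matrices (per-subject Poisson threshold plus group
    consistency), Fisher-z group averaging of functional correlations,
    modularity-based module detection with restarted Louvain optimisation,
    small-world verification against degree-preserving rewired null models,
    nonparametric two-cohort permutation tests across network densities,
    module-averaged task-contrast activity profiles, and network-level
    representational similarity analysis (activation and model dissimilarity
    matrices compared by second-order Spearman correlation). Includes a
    synthetic-data generator with a planted module structure so that every
    stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
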