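Package: piosphere
Title: Multi-Scale Ant Community Structure Along Distance-to-Water Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pitfall-trap surveys of ground-dwelling
    arthropod communities sampled along discrete distance-to-water gradients.
    Provides a validated data model for hierarchical trap surveys (transects,
    distance categories, sample points, traps, seasons), a synthetic survey
    generator with plantable abundance gradients and nested or modular spatial
    structure, Hill-number alpha diversity, multi-scale beta diversity as
    distance-to-centroid dispersion in a principal-coordinate embedding of
    modified Gower dissimilarities, weighted-interaction nestedness (WINE),
    weighted bipartite modularity optimised by simulated annealing,
    margin-constrained null-model inference, seasonal permutation comparisons
    of null deviations, and an orchestrating analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
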