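Package: surfacedepth
Title: Surface-Depth Generative Models for Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates, fits and inverts surface-depth network models, in
    which link weights are the product of a log-normal node fitness
    ("surface") factor and a latent Euclidean-space node similarity
    ("depth") factor. Provides the five normalised topology metrics
    (clustering, global efficiency, degree variance, Louvain modularity,
    degree assortativity) and a two-stage grid search that fits the model
    (and power-law fitness / spherical-geometry comparators) to an
    observed network by minimising the metric RMSE; recovers the hidden
    depth factor of a weighted network by skewness-minimising surface
    inversion; and assesses the geometric congruence of nearest-neighbour
    graphs built from recovered depth factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
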