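Package: litcohesion
Title: Literature Cohesion Analysis of Gene Sets via Latent Semantic Indexing
Version: 0.1.0
Authors@R: person("GCAT", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds per-gene documents from literature citations, models
    gene-gene functional similarity by latent semantic indexing (log-entropy
    term weighting, truncated singular value decomposition, cosine
    similarity), calibrates an empirical cosine edge threshold from random
    gene sets, and scores the functional cohesion of arbitrary gene sets
    with a one-sided Fisher's exact test p-value (the literature p-value,
    LPv). Includes a synthetic literature-corpus generator with known topic
    structure for validation, Cytoscape-compatible network export, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
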