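Package: pcnets
Title: Data-Driven Discovery of Primary Care Networks from Patient Registration Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies 'natural' communities of general practices (Primary Care
    Networks, PCNs) from patient registration patterns. Builds an LSOA-by-practice
    registration matrix with deduplication and exclusion rules, computes
    market-concentration statistics (Herfindahl-Hirschman index and equivalent
    market size), constructs a practice-practice cosine-similarity network,
    sparsifies it with the Relaxed Minimum Spanning Tree, partitions it by
    multiscale Markov-stability community detection with repeated Louvain
    optimisation and consensus selection, applies geographic validity filters to
    select an optimal partition over a (pruning parameter, Markov time) grid, and
    assigns small-area geographies to the resulting networks with catchment and
    coverage reporting. A synthetic-city generator with planted community structure
    makes the whole pipeline testable without restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
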