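Package: mobpso
Title: Non-Redundant Gene Marker Selection with Multiobjective Binary Particle Swarm Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects relevant and mutually non-redundant gene markers from
    two-class expression matrices by casting feature selection as a densest
    subgraph search on a complete feature-dissimilarity graph. Nodes are genes
    weighted by signal-to-noise-ratio relevance; edges are weighted by
    1 - Pearson correlation. A multiobjective binary particle swarm optimizer
    with Pareto non-dominated sorting, crowding distance and a bounded external
    archive maximizes average node weight and average edge weight of the
    selected subgraph simultaneously. Includes a tStat score for picking the
    final solution from the archive, consensus-marker extraction over repeated
    runs, a two-class synthetic expression-data generator with planted relevant,
    redundant and noise genes, and an evaluation suite (repeated hold-outs and
    stratified k-fold cross-validation with a linear support-vector machine).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
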