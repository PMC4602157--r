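Package: todag
Title: Timed Oncogenetic Directed Acyclic Graphs from Binary Mutation
    Co-Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers timed oncogenetic directed acyclic graphs (TO-DAGs) from
    cross-sectional binary co-occurrence matrices of somatic genetic events.
    Edges carry conditional-probability weights oriented from more to less
    frequently mutated events, waiting times drawn from exponential laws with
    rate equal to the stored conditional probability, and fast/moderate/slow
    speed categories. Includes generators for the synthetic benchmark families
    used to validate the model (random binary matrices, step-wise filled
    triangular matrices, disjoint and shared-event block designs, and
    accessible-pointed-graph gold standards with constraint-derived event
    probabilities), plus an evaluation suite (edge-recovery AUROC against gold
    standards, degree assortativity, transitivity, Kleinberg hub/authority
    scores, degree/strength tables, induced subgraphs) and GraphML/TSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
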