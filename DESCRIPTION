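Package: mptf
Title: Transcription Factor Module Activity Across Disease Stages in
    Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies progression-associated transcription factors (TFs)
    from grouped single-cell expression data. Integrates a curated TF-target
    edge list with a protein-protein interaction network, mines a gene module
    for every TF by random walk with restart, filters modules by induced
    subnetwork connectivity and hypergeometric overlap with the TF's curated
    targets, scores each module's activity per (cell type, stage) group as a
    weighted mean of relative expression with outlier exclusion, assigns
    significance by label permutation, classifies per-TF activity
    trajectories across ordered disease stages, and tests modules for
    enrichment in trajectory-associated gene lists. A negative-binomial
    synthetic-data generator with planted modules and planted per-group
    activity shifts makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
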