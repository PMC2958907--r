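Package: pathmotif
Title: Pathway Map Parsing and Network Motif Enrichment for Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parses CellDesigner-flavoured SBML process diagrams of signaling
    pathways into a typed pathway model, projects the typed reactions onto a
    simple directed graph, and detects over-represented network motifs of
    sizes 3 to 6 (feedforward loops, bifans, multi-input convergence,
    feedback) against a degree-preserving edge-switch null ensemble using a
    z-score and empirical p-value criterion. Includes census and per-node
    annotation reporting for curated pathway knowledgebases, and seeded
    synthetic generators (typed pathway models and background digraphs with
    planted motif instances) for ground-truthed benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
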