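Package: motifspace
Title: Network Motif Mining with Incidence-Matrix Codes and Parity-Node
    Space Compression
Version: 0.1.0
Authors@R:
    person("motifspace", "authors", email = "motifspace@example.org",
           role = c("aut", "cre"))
Description: Mines network motifs in directed biological networks
    (transcription-regulation graphs and similar). Enumerates all connected
    induced k-subgraphs with an ESU-style backtracking search, marks
    isomorphism classes by a canonical balanced-ternary integer Code derived
    from the vertex-edge incidence matrix, compresses the search space by
    collapsing structurally interchangeable (parity/twin) vertices with exact
    count recovery, and calls motifs against a degree-preserving edge-swap
    randomized ensemble using three classical significance criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
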