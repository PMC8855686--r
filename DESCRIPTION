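Package: hdgraph
Title: Hyperdimensional Graph Memory: Holographic Encoding, Decoding and Reasoning
Version: 0.1.0
Authors@R: person("hdgraph", "maintainers", email = "hdgraph@example.org", role = c("aut", "cre"))
Description: Encodes whole graphs (undirected, directed, weighted) into single
    high-dimensional integer hypervectors using a vector-symbolic architecture
    (bipolar atoms, componentwise binding, integer bundling, cyclic permutation),
    and decodes them back with thresholded similarity retrieval, iterative
    noise-cancellation reconstruction and memory refinement. Ships the
    closed-form Gaussian signal/noise capacity model that predicts when decoding
    succeeds (ROC curves, SNR, equal-error thresholds), graph-level reasoning
    (method-of-moments graph matching, hypervector-native shortest path),
    seeded synthetic graph generators, capacity-sweep simulation harnesses,
    plain-text serialization of graphs and memories, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
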