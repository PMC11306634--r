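Package: molcomplexity
Title: Coding-Based Complexity Measures for Molecular Data Representations
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes and compares complexity indexes on one-dimensional
    representations of molecular data: classic lossless coding schemes
    (run-length encoding, Huffman coding, LZ77/LZ78 parsing, LZW), block
    Shannon entropy, a string assembly index (exact minimal assembly
    pathway search plus greedy and analytic bounds), and a reduced-scale
    Coding Theorem Method table with the Block Decomposition Method.
    Includes seeded generators for modular ("biotic-like") versus random
    ("abiotic-like") strings, binarised peak matrices and molecule graphs,
    readers for MOL V2000 connection tables, bond distance matrices, and a
    statistics stage reporting pairwise Pearson correlations with
    one-tailed p-values and rank-based two-group separation (AUC, Cliff's
    delta).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
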