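Package: chainreasoner
Title: Property-Chain Reasoning over Linked Biological Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers implicit associations between entity classes in a linked
    biological knowledge graph (for example herb to gene, or herb to drug
    ingredient) by materializing OWL property chains over RDF instance triples.
    Three join algorithms are provided: a naive iterative join, a parity-rule
    algorithm that halves the property chain set every pass and so finishes in
    a logarithmic number of iterations, and a multichain variant that runs
    several chains through the same shared jobs. All three execute on a
    deterministic local map/shuffle/reduce engine and are verified against a
    brute-force path-enumeration oracle. Includes N-Triples and TSV readers and
    writers, a seeded generator of layered knowledge graphs with known ground
    truth, precision/speedup/sizeup evaluation helpers, and a small command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
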