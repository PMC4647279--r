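Package: rmsnet
Title: Reaction Molecular Signature Networks for Conserved Chemical
    Transformation Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Reaction Molecular Signatures (RMS) from reaction
    chemistry, classifies reactions by the chemical transformation they
    perform, reduces a main-compound reaction network into a directed RMS
    network with Markov transition probabilities, weights transformation
    classes by reaction diversity, topological importance (PageRank) and
    enzyme diversity, and enumerates and scores loop-free RMS paths to
    detect conserved chemical transformation modules via a Pathway
    Conservation Index.  Includes a seeded synthetic-data generator that
    emulates curated pathway-database inputs with planted conserved
    modules, so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
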