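Package: npnet
Title: Natural-Product Library Profiling and Drug-Target Network Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for profiling natural-product compound libraries and for
    network-pharmacology analysis of compound-target interaction data.
    Covers structure normalization and stereo-aware deduplication of
    SMILES/SDF libraries, Lipinski-style descriptor calculation and
    Rule-of-Five profiling, principal-component chemical-space mapping with
    overlap quantification, bipartite drug-target network construction from
    experimental affinities or docking-score tables (with reference-ligand
    admissibility filtering), degree/betweenness centrality and scale-free
    degree-distribution fitting, and a docking-score-weighted predictor of
    disease indications. Seeded synthetic-data generators emulate the
    descriptor distributions, scale-free interaction networks, and docking
    campaigns that the analysis assumes, so the full pipeline runs and is
    testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
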