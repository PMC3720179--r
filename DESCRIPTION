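Package: ponnet
Title: Protein Overlap Networks for Gene Ontology Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds protein overlap networks (PONs), in which two proteins are
    connected whenever they share a Pfam-style domain, and predicts Gene
    Ontology (GO) annotations of a query protein by counting the occurrence
    frequency of GO terms over its network neighborhood. Supports
    domain-based prediction from direct and second-layer neighbors,
    prediction from curated GO annotation (GAF) files, composite
    multi-genome networks, network topology statistics (degree, clustering
    coefficient, shortest paths, connected components), a randomization
    control, and a full evaluation protocol (success rate, top-1/top-3
    accuracy, predictable fraction, coverage, recall). Includes a synthetic
    genome generator with planted domain-module structure so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
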