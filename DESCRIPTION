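Package: fpgnn
Title: Multi-Task Fingerprint and Graph-Attention Neural Networks for
    Molecular Inhibition Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds multi-label molecular inhibition classifiers that combine
    a fingerprint neural branch (MACCS, PubChem-style substructure keys, and a
    pharmacophore ErG descriptor) with a graph-attention neural branch over the
    molecular graph, fused into a parameter-sharing multi-task head. The
    canonical configuration targets the five major cytochrome P450 isoforms
    (1A2, 2C9, 2C19, 2D6, 3A4). Includes dataset curation and structure-based
    cluster splitting, masked multi-task cross-entropy training, Y-scrambling
    validation, confusion-matrix and AUC evaluation, a k-nearest-neighbour
    Euclidean-distance applicability domain, attention and fingerprint-bit
    interpretation, a synthetic molecule generator with known structure-label
    rules, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
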