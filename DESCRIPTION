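Package: pathconsensus
Title: Pathway-Based Integration of Coupled Omics Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates coupled phosphoproteome, proteome and transcriptome
    time courses through prior pathway knowledge. Per time point, significant
    phosphoproteins are mapped downstream (pathway, transcription factor,
    target gene) and significant transcripts upstream (transcription factor,
    pathway, proteomic regulator); layer-wise intersections define consensus
    molecules. Static consensus networks connect consensus proteins and
    transcription factors in a confidence-weighted protein-protein interaction
    network via a shortest-paths Steiner-tree approximation, completed with
    TF-target and feedback edges. A dynamic consensus network is inferred from
    spline-densified time courses with an empirical-Bayes linear feedback
    state-space model, co-regulation patterns are found by fuzzy c-means time
    profile clustering, and phosphoprotein-anchored transcript/protein time
    courses are integrated. Includes a synthetic-data module that generates
    knowledge bases and coupled time courses with planted signaling cascades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
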