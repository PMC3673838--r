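Package: aerograph
Title: Evidence Graphs for Translational Research Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents a translational research program as a phase-stratified,
    time-ordered directed acyclic graph of studies: nodes are individual study
    reports coded by outcome (positive, negative, inconclusive) and status
    (completed or contemplated), and directed edges record intellectual
    lineage from parent to child study. Provides robustness analytics over
    the graph -- within-phase consistency, along-path concordance, de-facto
    phase-transition thresholds, orphaned studies, maximal same-outcome
    sub-trajectories, and positive-to-negative trend ratios -- together with
    what-if planning for contemplated future studies, readers and writers for
    study tables (CSV/TSV/JSON) and graph exchange formats (DOT, GraphML),
    a layered time-by-phase visualization (SVG, DOT, ggplot2), packaged
    example programs, and a seeded synthetic program generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
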