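Package: coretier
Title: Tiered Core Microbiota Diagnosis and Partition-Aware Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses core members of host-associated microbial
    meta-communities with a two-level prevalence threshold (core-prime
    within subcommunities, core among subcommunities), validates the
    resulting core sets against bootstrap-subsampled communities via a
    Jaccard-agreement threshold sweep, and labels maximal agreement
    intervals as core tiers. Downstream, partition-aware community
    assembly analyses compare the chosen core and noncore partitions:
    a Sloan neutral community model fit with bootstrap confidence bands
    and per-taxon classification, dissimilarity-overlap curves with
    change-point detection and permutation nulls, per-subcommunity
    Spearman co-occurrence networks combined by cross-subcommunity edge
    frequency, and a three-term weighted graph dissimilarity. A seeded
    synthetic meta-community generator with planted core, epidemic and
    rare taxa provides ground-truth-labelled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    biomformat,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
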