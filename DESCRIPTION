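Package: coevclust
Title: Interdependent Site Clustering and Pattern Discovery in Protein
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers clusters of mutually interdependent aligned sites in
    protein-family multiple sequence alignments. Pairwise interdependency is
    measured by the normalized mutual information (redundancy) between
    alignment columns; sites are partitioned by a k-modes attribute-clustering
    algorithm swept over all cluster counts k; statistically significant
    amino-acid patterns within each cluster are found via adjusted residuals;
    and the clusters across the k-sweep are assembled into a hierarchical
    cluster tree with branches, nodes, modules and representative clusters.
    Includes a seeded synthetic-alignment generator with planted dependent
    blocks and patterns for validation, broom-style tidiers and ggplot2
    autoplot methods, and an end-to-end pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
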