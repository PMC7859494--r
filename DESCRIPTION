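Package: htqs
Title: Spike-In Absolute Quantification and Dual-Branch Analysis of 16S
    rRNA Amplicon Communities
Version: 0.1.0
Authors@R:
    person("HTQS", "Maintainers", email = "maintainers@htqs.dev",
           role = c("aut", "cre"))
Description: Converts 16S rRNA amplicon OTU read counts to absolute gene
    copies per liter using synthetic spike-in internal standards, and runs
    the paired relative/quantitative community analyses used in marine
    microbial ecology: per-sample log-log standard curves, alpha diversity
    (richness, Chao 1, Shannon, Faith's phylogenetic diversity),
    Bray-Curtis ordination with Procrustes agreement tests, signed Spearman
    co-occurrence networks with graph attributes, Mantel tests, RDA-based
    variation partitioning, and sparse partial least squares selection of
    taxon-variable associations. Includes a seeded synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
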