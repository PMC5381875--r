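Package: rhizonet
Title: Downstream Analysis of Rhizosphere 16S rRNA Amplicon Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the downstream analysis of taxon-by-sample
    amplicon count tables from rhizosphere soils: rarefaction-normalized alpha
    diversity (observed richness, Good's coverage, Chao1, Shannon), Bray-Curtis
    and weighted UniFrac beta diversity with principal coordinates analysis,
    taxon dominance classification and shared-genus accounting, diversity-pH
    regression, redundancy analysis of abundant genera against soil chemistry,
    and thresholded Spearman co-occurrence network construction with exact
    small-sample permutation P-values, hub detection, topology and
    phylum-incidence statistics. Includes a compositional community simulator
    (pH gradient, taxon responses, planted correlated genus blocks) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
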