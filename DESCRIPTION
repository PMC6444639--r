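Package: bgcqtl
Title: Linking Predicted Plant Biosynthetic Gene Clusters to Metabolite QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A genetical-metabolomics toolkit for bioprospecting plant
    biosynthetic gene clusters (BGCs). Maps untargeted metabolite features as
    quantitative traits in recombinant inbred line (RIL) populations
    (single-marker LOD scans, permutation thresholds, LOD-drop support
    intervals) and in association panels (marker regression with principal
    component structure covariates and Benjamini-Hochberg FDR control),
    superimposes the resulting mQTL intervals on predicted gene clusters,
    attaches evidence layers (multi-mQTL and multi-gene support, coexpression
    of cluster genes, mass-difference linkage of metabolite features), and
    classifies and ranks candidate BGC-metabolite links for follow-up. Ships
    a seeded synthetic-data generator (genomes with planted clusters, RIL and
    structured GWAS populations, heritable traits, mass-decorated features,
    coexpressed expression matrices) so the whole workflow is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
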