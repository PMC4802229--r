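Package: kinasedep
Title: Mapping Kinase Genetic Dependencies from Arrayed siRNA Viability Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for turning plate-arrayed siRNA viability
    screens of cancer cell line panels into kinase genetic dependencies
    (KGDs). Raw plate luminescence is normalized per plate, summarized over
    replicates and standardized with a robust Z score; screens are quality
    controlled with Z'-factor and replicate-correlation filters; dependencies
    (Z <= -2) are associated with tumor histotypes, driver-gene alterations
    and pathway-level (logical-OR) mutation groupings using one-sided median
    permutation tests with Benjamini-Hochberg false discovery control;
    candidate driver-dependency pairs are annotated on typed
    protein-interaction networks (direct links, shortest directed paths,
    within-set connectivity enrichment); and drug sensitivity is compared
    between genotype groups via dose-response AUC and one-sided Mann-Whitney
    tests. A fully specified synthetic-data generator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    data.table,
    igraph,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
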