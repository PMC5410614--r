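Package: ssrmta
Title: SSR Association Mapping for Grain Micronutrient Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete association-mapping workflow for multiallelic SSR
    panels phenotyped for grain iron and zinc concentration across
    multi-environment trials. Provides per-locus diversity statistics
    (allele numbers, Nei gene diversity, PIC), maximum-likelihood admixture
    inference with Evanno delta-K model selection, neighbor-joining trees,
    principal coordinate analysis, allele-sharing kinship, AMOVA,
    multiallelic linkage disequilibrium, general and Q+K mixed linear model
    marker scans with Bonferroni-style thresholds, favorable-allele effect
    mining, and cross-pyramiding proposals. Includes a synthetic-panel
    generator with admixed population structure and planted marker-trait
    associations for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
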