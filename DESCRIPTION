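Package: protistnet
Title: Habitat Comparison and Co-Occurrence Networks for Protist
    Metabarcoding OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream statistical analysis of protist (18S V4)
    metabarcoding OTU tables from two connected habitats: replicate
    pooling, singleton removal, rarefying normalization, alpha-diversity
    and rarefaction curves, Bray-Curtis and Hellinger transforms, the
    shared/exclusive habitat partition, CLAM multinomial
    generalist/specialist classification, maximal information coefficient
    (MIC) co-occurrence network inference with permutation significance
    and random-graph null comparison, hub identification, and rule-based
    trophic annotation.  Includes a synthetic community generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
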