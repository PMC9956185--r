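Package: ecoassembly
Title: Diversity, Distance Decay, and Null-Model Community Assembly for
    Plankton Metabarcoding Surveys
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream community ecology of eukaryotic
    plankton metabarcoding surveys in coastal waters: OTU table input and
    validation, taxonomy confidence filtering, dominant-taxon summaries,
    Shannon alpha diversity with environment correlations, Bray-Curtis
    beta diversity and nonmetric multidimensional scaling, geographic
    distance-decay of community similarity, and a two-stage phylogenetic
    null model (beta nearest taxon index followed by Raup-Crick
    Bray-Curtis) that classifies pairwise community turnover into
    selection, dispersal, and drift-dominated assembly processes.  A
    synthetic metacommunity generator produces phylogenies, estuarine
    environmental gradients, and OTU tables under controlled assembly
    regimes so that every stage of the pipeline can be verified without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
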