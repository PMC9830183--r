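Package: castemeta
Title: Cross-Species Transcriptome Meta-Analysis of Reproductive Division of Labour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A standardized pipeline for detecting conserved "genetic toolkit"
    genes distinguishing reproductive from non-reproductive phenotypes across
    multiple social insect species. Assembles orthogroup-level expression
    matrices from per-species RNA-seq counts and an OrthoFinder-style
    orthology map, applies a species-aware variance-stabilizing
    transformation, and combines three detection routes: principal-component
    trait screening with a randomized-phenotype control, leave-one-species-out
    support-vector-machine recursive feature elimination, and consensus
    weighted gene co-expression networks with meta-analytic trait association
    and a label-shuffle resampling null, alongside per-species
    negative-binomial differential expression. Includes a multi-species
    synthetic count generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
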