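Package: reservescan
Title: Profile-Model Screening of Bacterial Proteomes for Energy-Reserve
    Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens bacterial proteomes for the key enzymes of the five
    major microbial energy reserves (polyphosphate, glycogen, wax esters,
    triacylglycerols and polyhydroxyalkanoates) with position-specific
    profile models: homolog-set dereplication, progressive alignment,
    terminal trimming and model estimation; local Viterbi search with
    Gumbel E-value calibration and strict E-value/coverage acceptance
    thresholds; pathway presence/absence calling including the two
    Pfam-defined PhaC synthase groups; proteome-size contrasts between
    pathway-positive and pathway-negative groups; and export of
    taxonomy-tree annotation files. A synthetic-cohort generator with
    planted homologs, decoys, clade structure and a controlled
    proteome-size effect makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
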