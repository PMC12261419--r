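Package: taxcycle
Title: Coarse-Grained Biogeochemical Cycle Functions from Taxonomic
    Affiliations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts coarse-grained metabolic functions of microbial
    communities (methanogenesis, acetogenesis, sulfate reduction, ...)
    from metabarcoding taxonomic affiliations. Affiliations are resolved
    against a precomputed archive of per-taxon consensus proteomes with
    most-specific-rank-first fallback; marker enzymes are detected in the
    consensus proteomes with profile hidden Markov models scored by a
    local Viterbi dynamic program; Boolean AND/OR rules over marker
    profiles call functions per taxon; per-sample occurrence and
    abundance-weighted profiles are aggregated and projected onto carbon,
    nitrogen and sulfur cycle diagrams. Includes a seeded synthetic
    community generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    zip
LinkingTo:
    Rcpp
Suggests:
    optparse,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
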