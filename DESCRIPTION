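Package: matrikin
Title: Kinship and Matrilineal Social Structure from Pseudo-Haploid Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the genetic kinship and social structure of
    small endogamous communities from low-coverage ancient DNA. Implements the
    windowed pairwise-mismatch (P0) relatedness statistic with median-normalised
    degree cutoffs, a (k0, k1, k2) relationship-model likelihood classifier,
    similarity-score haplogroup assignment against a marker-annotated tree,
    Simpson diversity of uniparental lineages, a renewal-coalescent simulator of
    runs-of-homozygosity tract lengths with a closed-form expectation and Poisson
    maximum-likelihood estimation of effective population size, and permutation
    tests for lineage-cemetery association, within- versus between-cemetery
    relatedness, and burial-distance independence. A pedigree-based synthetic
    community generator with exact truth tables (degrees, identity-by-descent
    segments, runs of homozygosity) makes every inference stage testable without
    access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    readr,
    ggplot2,
    generics,
    ape,
    vegan,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
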