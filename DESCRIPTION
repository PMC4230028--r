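Package: gblupd
Title: Genomic Prediction and Mate Allocation with Additive and Dominance Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dominance-aware genomic evaluation for single-generation cohorts
    of genotyped animals. Builds pedigree (A), genomic additive (G, VanRaden)
    and genomic dominance (D) relationship matrices, estimates additive and
    dominance variance components by average-information REML and by Gibbs
    sampling at the animal and the marker level, tests dominance variance with
    the boundary-corrected mixture chi-square likelihood ratio test, predicts
    breeding values and total genetic values with cross-validation, and plans
    matings by expected offspring total genetic value under per-sire capacity
    constraints. Includes a gene-dropping simulator of half-sib/full-sib cow
    cohorts with Hardy-Weinberg founder genotypes and weighted residuals for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
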