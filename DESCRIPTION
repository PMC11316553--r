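Package: strainani
Title: Strain-Identity Inference from Subsampled-Assembly ANI Null Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Distinguishes unrelated, related, and identical bacterial strains
    by building a same-strain null distribution of average nucleotide identity
    (ANI) from replicate genome assemblies of subsampled read sets, and
    projecting observed assembly-pair ANI values onto that distribution as
    left-tail empirical P-values. Ships a fragment-based k-mer ANI estimator,
    a synthetic genome/read/assembly simulator with a majority-vote
    consensus-error model, seeded read-pair subsampling with disjoint
    replicate pairing, SNP counting and pairwise identity from whole-genome
    alignments, and CRISPR spacer-array equivalence testing tolerant of
    strand flips and arrays split across contigs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
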