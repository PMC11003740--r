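Package: tcrep
Title: TCR-Alpha Repertoire Diversity, Overlap, and CDR3 Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing UMI-corrected T cell receptor alpha
    clonotype tables from multi-challenge, multi-tissue mouse studies:
    depth-normalised diversity estimation (observed richness, bias-corrected
    Chao1, normalised Shannon-Wiener evenness), frequency-weighted repertoire
    overlap (F2 metric) with multidimensional scaling and dendrograms, CDR3
    sequence-homology motif clustering against a V(D)J recombination null
    model, matched-pair quantification of clonal sharing between conventional
    and regulatory effector CD4+ T cell subsets, and invariant NKT clonotype
    tracking. A synthetic cohort generator with planted convergent motifs,
    tissue-resident motifs, subset-shared clonotypes and an invariant NKT
    spike makes every pipeline stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    readr,
    igraph,
    ape,
    Biostrings,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    MASS,
    jsonlite,
    vegan
Config/testthat/edition: 3
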