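Package: cisenrich
Title: Motif and ChIP Enrichment Analysis of Gene Sets by Windowed
    Genome Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate transcriptional regulators of a user
    gene set. The genome is tiled into fixed-length overlapping windows
    and each window is scored for the presence of a transcription factor
    motif with a block-HMM likelihood-ratio score that integrates strong
    and weak binding sites, or for occupancy with windowed ChIP signal.
    Profiles are rank-normalized (optionally within G/C-content bins),
    optionally averaged across species with phylogenetic weights and
    masked by a chromatin-accessibility filter. Per-gene regulatory
    scores over fixed, nearest-TSS or gene-territory regions define
    top-K target gene sets, which are tested for overlap with user gene
    sets by one-sided Fisher's exact tests. Includes a seed-deterministic
    synthetic benchmark generator with planted motif sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
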