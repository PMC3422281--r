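Package: mirdep
Title: miRNA Target Discovery in miRNA-Depleted Embryonic Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for identifying
    microRNA targets in Dgcr8-depleted (miRNA-deficient) embryonic stem
    cells. Provides small RNA-seq read filtering, ncRNA class assignment
    and ncRNA-anchored depth normalization, Dgcr8-independence calling,
    seed-gated target calling with signal-to-noise and sensitivity
    statistics, ranked-list k-mer (seed) enrichment landscapes with
    Markov composition correction, preranked gene-set enrichment with
    permutation significance, and a network-influence analysis combining
    triangle-weighted k-nearest-neighbour graph sparsification, two-level
    Markov clustering and per-target-list cluster support scores. A
    synthetic-data module generates every input the pipeline consumes so
    all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
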