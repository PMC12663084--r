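Package: phylotaxa
Title: Primer-Aware Taxonomic Assignment of Amplicons by Phylogenetic
    Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies marker-gene amplicons (for example 16S rRNA
    hypervariable regions) by placement into a primer-specific reference
    phylogeny whose interior nodes carry taxonomic labels. Per-rank
    cophenetic distance thresholds are optimized on the reference tree by
    minimizing over-merging and over-splitting errors, tip taxonomy is
    propagated to interior nodes with a binomial dominance model that
    permits one-to-many (ambiguous) labels, and queries are aligned,
    placed (via jplace files or a built-in distance-based placer), and
    assigned label sets per rank. Includes an ambiguity-aware evaluation
    harness and a synthetic fixture generator so the whole pipeline can
    be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
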