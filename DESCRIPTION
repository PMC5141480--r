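Package: subtypekit
Title: Molecular Subtype Discovery and Nearest-Centroid Classification for
    Bladder Cancer Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reproducing a luminal/basal molecular-subtype analysis of
    urothelial carcinoma expression data: median-of-ratios library-size
    normalization, signature-restricted agglomerative clustering with marker-panel
    labelling (luminal, basal, non-type), ClaNC-style nearest-centroid classifier
    training and prediction with a transdifferentiation shift score, cross-cohort
    centroid concordance by Spearman correlation, per-gene moderated two-group
    differential expression with Benjamini-Hochberg FDR and a replicated
    transcription-factor screen, and downstream ChIP-seq analysis (replicate peak
    consensus, window extraction, position-weight-matrix scanning, motif
    enrichment by one-sided Fisher tests). A seeded synthetic-data module
    generates expression cohorts with planted subtype structure, batch shifts and
    partial transdifferentiation, plus replicate peak sets with planted motif
    instances, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
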