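Package: receptr
Title: Uterine-Receptivity Transcriptomics Pipeline with Synthetic Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-condition bulk RNA-seq
    analysis of uterine receptivity: fold-change/p-value differential
    expression calling with Pearson/UPGMA heatmap ordering, delta-delta-Ct
    qRT-PCR concordance, hypergeometric over-representation testing with
    Benjamini-Hochberg FDR, position-weight-matrix promoter scanning and
    per-direction transcription-factor binding-site enrichment, scored
    interaction-network hub detection by the mean-plus-two-SD degree rule,
    connectivity-map style Kolmogorov-Smirnov drug-reversal scoring with
    permutation p-values, and cross-species ortholog concordance
    classification. Seeded synthetic-data generators plant known structure
    for every stage so the whole pipeline is benchmarkable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
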