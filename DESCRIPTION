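Package: proteostrat
Title: Proteogenomic Stratification of Leukemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for multi-omics patient
    stratification in chronic lymphocytic leukemia (CLL). Provides a
    synthetic cohort generator with planted proteomic subgroups,
    empirical-Bayes moderated differential abundance, resampling-based
    consensus clustering, percent-spliced-in (PSI) splicing statistics
    with a permutation null for the number of significant events,
    rank-based k-top-scoring-pairs and PLS-DA subtype classifiers with
    cross-platform missing-feature handling, survival analysis
    (Kaplan-Meier, log-rank, Cox with interactions), and protein
    co-abundance network modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
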