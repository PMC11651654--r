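Package: nucleocall
Title: Promoter-Centered Nucleosome-Resolution Chromatin Interaction Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes promoter-captured MNase proximity-ligation data from
    ligation-pair records to called promoter-anchored chromatin interactions.
    Classifies and deduplicates read pairs, builds consensus capture viewpoints
    from replicate mononucleosomal peak sets, aggregates distal pairs into
    occupancy- and viewpoint-normalized 250-bp contact records, fits a
    per-distance-rank Weibull background model and calls significant
    viewpoint-bin interactions. Includes distance-preserving permutation
    machinery for feature-enrichment and TAD-boundary analyses, CTCF motif
    orientation analysis, hierarchical clustering of promoter-interacting
    regulatory elements by factor-binding profiles, greedy forward feature
    selection with random-forest models of contact strength, benchmarking of
    interaction calls against CRISPRi-verified enhancer-promoter pairs, and a
    synthetic-experiment generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    ranger,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
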