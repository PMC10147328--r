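Package: hilcis
Title: Expression Inheritance and Cis-Trans Regulatory Divergence in
    Hybrid Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers expression-inheritance classes (dominant, additive,
    transgressive, conserved) and cis/trans regulatory-divergence classes
    (trans-only, compensatory, combined) for genes in homozygous X-linked
    hybrid introgression lines (HILs) of Caenorhabditis nigoni carrying
    C. briggsae DNA, from replicated RNA-seq count matrices. Includes
    negative-binomial pairwise contrasts with Benjamini-Hochberg correction,
    introgression-boundary detection from dual-reference mapping deltas,
    cross-HIL overlap and concordance statistics (Jaccard, hypergeometric,
    Fisher), and a negative-binomial synthetic-data generator with per-gene
    regulatory architectures and ground truth, so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
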