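Package: methyltrx
Title: Integration of DNA Methylation, Transcription-Factor Networks and
    Compound Signatures for Chronic Brain-Injury Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline asking whether chronic post-injury
    gene-expression changes are controlled by promoter/exon/gene-body DNA
    methylation or by transcription factors. Provides strand-aware promoter,
    exon and gene-body window construction from GTF/BED12 annotation,
    region-level read counting, a self-contained negative-binomial Wald
    differential test with median-of-ratios normalization and
    Benjamini-Hochberg FDR, preranked gene set enrichment analysis with the
    weighted Kolmogorov-Smirnov statistic and gene-tag permutation FDR,
    methylation-expression mediation regression with bootstrap confidence
    intervals, regulon dysregulation counting on a directed transcription
    factor network, a connectivity-map-style top-k compound-signature query,
    the small validation statistics (exact Mann-Whitney U, ddPCR
    reference-gene normalization, pyrosequencing percent methylation,
    marker correlation), a synthetic-data generator with planted recoverable
    structure, and a deterministic staged pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
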