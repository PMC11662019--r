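Package: regmir
Title: Super-Enhancer, G-Quadruplex and Chromatin-Loop Analysis for
    Nuclear miRNA Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative regulatory-genomics toolkit for studying how a
    nuclear microRNA shapes chromatin: quantile-based breadth classification
    of histone-mark domains (broad/medium/narrow H3K4me3), ROSE-style
    super-enhancer calling with hockey-stick cutoff and miRNA occupancy
    marking, G4Hunter-style G-quadruplex propensity scoring and peak
    filtering, HiChIP-derived promoter-enhancer loop and interaction-hub
    analysis with condition-response k-means clustering, and the shared
    enrichment statistics (Fisher exact tests, RPKM quantification,
    differential-expression classification, z-score matrices). A seeded
    synthetic-data generator with planted ground truth exercises the whole
    pipeline end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
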