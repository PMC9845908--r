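Package: matprov
Title: Maternal RNA Provisioning Analysis for Paired Oocyte and Egg Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for studying maternal mRNA and miRNA
    provisioning in paired oocyte and early-egg samples. Provides
    expression filtering and trimmed-mean-of-M-values (TMM) normalization,
    precision-weighted moderated differential expression under a
    non-intercept group model with season, condition and interaction
    contrasts, weighted gene-coexpression module detection with
    topological-overlap clustering and module-trait correlation,
    cross-tissue module correspondence statistics (hypergeometric tests,
    representation factors and a size-aware bootstrap null), miRNA locus
    curation with seed-aware homolog matching, consensus miRNA-target
    calling, reciprocal-best-hit ortholog detection, and a synthetic-data
    generator that emulates the paired two-tissue design with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    withr
Config/testthat/edition: 3
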