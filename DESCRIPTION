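Package: lncnet
Title: Conserved lncRNA-mRNA Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("lncnet", "maintainers", email = "lncnet@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying conserved lncRNA-mRNA
    interactions across multiple treatment transcriptomes: stepwise long
    non-coding RNA cataloguing from assembled transcripts (length, open
    reading frame and coding-evidence filters), negative-binomial
    differential expression against merged controls, weighted co-expression
    network construction with topological-overlap similarity, module
    eigengene and module-trait analysis, gene-set over-representation with
    the EASE-modified Fisher statistic, and extraction of the interaction
    pairs conserved across all treatment groups.  Includes a synthetic-data
    generator with planted modules, trait effects and conserved hub pairs
    so every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
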