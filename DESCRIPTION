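Package: editome
Title: Discovery and Characterization of A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for detecting adenosine-to-inosine (A-to-I)
    RNA editing sites from aligned RNA-seq data. Implements candidate
    mismatch calling from quality-filtered pileups, a sequential filter
    cascade (genomic variant removal, multi-mismatch window filtering,
    cluster selection with cross-study rescue of isolated sites),
    mismatch-spectrum based false-discovery estimation, hyper-editing
    detection through base-transformed alignment, repeat editing indices
    modeled after the Alu editing index, context-specific site calling,
    high-confidence coding-site derivation with recoding annotation,
    chain-file liftover with cross-species conservation classification,
    and long-read co-editing phasing. A synthetic-data generator with a
    planted truth editome supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    vcfR,
    S4Vectors,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
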