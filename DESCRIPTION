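Package: pollensmrna
Title: Small RNA Analysis of Pollen Development in Diploid and
    Autotetraploid Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis workflow for
    comparing miRNA and siRNA populations across pollen development
    stages (pre-meiotic interphase, meiosis, single microspore) in
    diploid and autotetraploid rice.  Implements raw-tag preprocessing
    and ncRNA filtering, miRNA identification against precursor
    hairpins with isomiR variant naming (end offsets and internal
    substitutions), a median-reference regression-based copy-number
    normalization, Fisher/chi-square differential miRNA expression
    calling with stage-specific and Venn accounting, plant miRNA target
    complementarity scoring with G:U wobble penalties, transposable
    element associated 24-nt siRNA abundance profiling, and
    hypergeometric term enrichment.  A synthetic study generator
    emulates the two-genotype by three-stage design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stringi,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
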