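Package: rnaeditome
Title: RNA-Seq-Only Discovery of A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filter-cascade pipeline for discovering adenosine-to-inosine
    (A-to-I) RNA editing sites from per-sample RNA-seq variant calls alone,
    without matched DNA. Starting from VCFs with allele depths and GATK-style
    site annotations, the pipeline removes known SNPs, applies quality and
    allele-ratio filters, screens sequence context (simple sequence repeats,
    homopolymers, splice-junction proximity, bidirectional transcription,
    flank uniqueness), requires recurrence across individuals, detects
    hyper-editing clusters and extends the editome by recruiting nearby
    variants, annotates genomic region and coding consequence, summarises the
    twelve-way mismatch spectrum and tissue statistics, builds neighbour
    preference matrices, and validates flanks against EST or known-editome
    sequence sets. A seeded synthetic-study generator with a planted-site
    truth ledger supports recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
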