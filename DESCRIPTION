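Package: ncorfTSA
Title: Quantifying Noncanonical-ORF-Derived Tumor-Specific Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify tumor-specific antigens derived from
    noncanonical open reading frames (ncORFs) in paired tumor/normal
    cohorts. Enumerates candidate ncORFs on lncRNAs and unannotated
    transcripts, calls translated ORFs from P-site-resolved ribosome
    profiling via a transparent periodicity-and-homogeneity score,
    estimates class-level translation indices, classifies transcripts as
    tumor-specific through a matched-normal and healthy-tissue-panel
    filter cascade, enumerates HLA-I 9-mer strong binders per patient
    (pluggable affinity predictor with a deterministic built-in
    surrogate), applies a self-peptide cross-match filter, computes
    translation-index-corrected antigen loads with shared/private
    accounting, shortlists frequent candidates and tests HERV overlap
    enrichment. Includes a fully labelled synthetic cohort generator so
    the complete pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
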