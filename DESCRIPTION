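Package: slimscreen
Title: Short Linear Motif Screening and Gene-Set Enrichment over Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles PROSITE/fuzzpro-style short linear motif (SLiM)
    patterns, scans multi-isoform protein FASTA proteomes for all matches,
    and quantifies the bidirectional percent enrichment of motif-bearing
    genes within a gene set such as circadian transcripts, together with a
    hypergeometric and permutation significance layer, ortholog motif
    conservation reports, and a synthetic-proteome generator with planted
    motif enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
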