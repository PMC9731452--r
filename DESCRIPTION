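Package: capstart
Title: Analysis of mRNA 5' Terminal Sequences in Transcription, Translation
    and Decay
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and interpreting the first transcribed
    nucleotides of mRNAs. Implements 5'-end read classification against a
    randomized-7-mer reporter construct with correction for the
    reverse-transcriptase non-templated G artifact and exclusion of
    ambiguous +1 G sequences, normalized per-7-mer expression, polysome
    (translation) and Actinomycin-D chase (decay) log2-ratio estimation
    under control and mTOR-inhibited conditions, IUPAC motif-class
    statistics (Inr, TCT, TOP), pyrimidine-run and substitution-scan
    analyses, CAGE-style promoter-window k-mer frequencies on genomic tag
    data, and a fully parameterized synthetic-data generator with ground
    truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
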