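Package: ampligrep
Title: Probe-Based Retrieval and Editing-Outcome Quantification for
    Barcoded Long-Amplicon Nanopore Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrieves full-length reads of barcoded long-range PCR
    amplicons from error-prone nanopore sequencing pools using sets of
    short overlapping k-mer probes matched exactly against each read,
    demultiplexes the retrieved reads by barcode-primer probes, and
    quantifies gene-editing outcomes: short double-stranded
    oligodeoxynucleotide (dsODN) insertions, plasmid-backbone
    integration in either orientation, homology-directed-repair (HDR)
    knock-in efficiency and large-deletion frequency from CIGAR
    operation lengths of alignments. A companion simulator generates
    nanopore-like reads with per-base substitution, insertion and
    deletion errors, truncated and over-long read artifacts, and spiked
    edits at known frequencies, so the whole pipeline is testable with
    exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
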