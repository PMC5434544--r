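Package: ribosig
Title: Prokaryotic Translation Signal Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide profiling of prokaryotic translation signals.
    Extracts coding sequences with upstream and downstream flanks from
    annotated genomes (GenBank flat files or FASTA plus GFF3), scans
    upstream windows for Shine-Dalgarno / anti-Shine-Dalgarno pairings
    against the 3' tail of small-subunit rRNA and summarises them with the
    D-to-start spacing statistic, computes the index of translation
    elongation (I_TE) and the codon adaptation index (CAI) under four
    synonymous-codon-family treatments, and builds sliding-window
    folding-energy profiles around start and stop codons. A synthetic
    genome generator with planted motifs, codon bias and hairpins supports
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
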