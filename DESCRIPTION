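Package: cubkit
Title: Codon Usage Bias Analysis for Organelle Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias in sets of
    protein-coding sequences, with an emphasis on chloroplast genomes.
    Extracts and quality-filters CDSs from GenBank or FASTA input, computes
    nucleotide-composition statistics (A3/T3/C3/G3, GC1-GC3, GC3s), the
    classical bias indices (RSCU, Wright's effective number of codons, CAI,
    CBI), identifies high-frequency and optimal codons via the
    ENC-decile delta-RSCU procedure, and provides the standard
    mutation-versus-selection diagnostics: the ENC-GC3s plot with Wright's
    expectation curve, the ENC ratio distribution, the PR2 bias plot, and
    the neutrality (GC12-GC3) regression. Correspondence analysis of
    per-gene RSCU profiles with Axis-1 correlation follow-up is included,
    together with a synthetic CDS generator with planted compositional and
    selective structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
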