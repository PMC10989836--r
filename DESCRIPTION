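Package: primerpanel
Title: Minimal Degenerate Primer Panels for Ultra-Multiplex PCR and
    Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic design of minimal, mismatch-tolerant, dimer-vetted
    degenerate primer sets for ultra-multiplex PCR and targeted
    next-generation sequencing over large, diverse nucleotide sequence
    collections. Implements an IUPAC ambiguity-code value algebra with a
    position-aware mismatch metric (Y-distance), greedy identity-based
    clustering, per-cluster multiple alignment and window scanning, a
    nearest-neighbour/Viterbi degenerate primer design model, an empirical
    primer-dimer loss function with risk classification, seed-index host
    specificity screening, greedy assembly of a compatible intercluster
    primer set, and an in-silico PCR evaluation layer with coverage and
    efficiency reporting. A synthetic sequence-family generator supports
    fully reproducible, download-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
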