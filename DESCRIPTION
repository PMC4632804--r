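Package: dnassign
Title: DNA Molecular-Computing Simulation of the Unbalanced Assignment Problem
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico simulator of Adleman-Lipton test-tube computing
    applied to the unbalanced assignment problem (n jobs, m < n individuals,
    minimum total cost). Provides a symbolic strand and tube algebra with the
    twelve classical tube operations, the five-step strand-filtering pipeline
    that solves the assignment instance by length selection, an exact
    brute-force combinatorial oracle for verification, constraint-based DNA
    codeword design (three-letter alphabet, homopolymer-run limits,
    distinctness), nearest-neighbor duplex thermodynamics for probe/library
    hybridization, and a small command-line interface with CSV/FASTA/TSV/JSON
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
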