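Package: unisig
Title: Unique DNA Signature Discovery by Incremental Hamming-Distance Filtration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers unique oligonucleotide signatures -- fixed-length DNA
    patterns that occur at exactly one position of a sequence database and lie
    at Hamming distance greater than a mismatch tolerance d from every pattern
    at any other position.  Implements pigeonhole-partition discovery kernels
    (the UO and IMUS parameterizations), incremental discovery that re-verifies
    previously found signatures as candidates instead of rescanning the whole
    database, a linear-time partial-partition scheduling heuristic (PEL) with a
    greedy earliest-available dispatcher for parallel task lists, and an
    iterative driver that enumerates every implicit signature of length at most
    l and tolerance at least d.  Includes a seeded synthetic-database generator
    with planted near-duplicates for validation, and a brute-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
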