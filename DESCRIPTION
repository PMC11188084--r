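Package: meioc
Title: Meiotic Chromatin Contact-Map Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of binned chromosome-conformation (Hi-C / Micro-C)
    contact maps through the mitotic-to-meiotic transition: matrix
    construction from pairs files, ICE-style balancing, distance-decay
    P(s) curves with log-log derivatives and loop-size / cohesin-density
    estimation, insulation scores with Li-threshold TAD boundary calling,
    A/B compartment eigenvectors with GC orientation and local compartment
    ranks, contamination-sensitivity scans, and anchor-centric aggregation
    (dot calling, CTCF orientation annotation, stripe-bias profiles,
    promoter/enhancer pileups). Includes a synthetic contact-map generator
    with known compartment, loop-array, dot and stripe structure plus
    closed-form expectations, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
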