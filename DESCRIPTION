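Package: its2eval
Title: Evaluation of the ITS2 Region as a DNA Barcode
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the internal transcribed spacer 2 (ITS2) of the
    nuclear ribosomal cistron as a DNA barcode. Provides profile-based
    delimitation of the ITS2 core between conserved 5.8S and 28S anchor
    segments, reference-database curation (length, ambiguity and naming
    filters, monotypic-genus exclusion, fungal-contaminant screening,
    per-species consensus barcodes), Kimura 2-parameter divergence statistics
    (pooled and per-taxon intra- and inter-specific distances, theta, theta
    prime, coalescent depth), and top-hit (BLAST1-style) species
    identification with leave-one-out success-rate evaluation. A seeded
    simulator generates taxonomically structured ITS2 datasets with known
    ground truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
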