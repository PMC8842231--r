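Package: tripscar
Title: Analysis of Barcoded Double-Strand-Break Repair Reporter Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed barcoded reporter assays of DNA
    double-strand-break repair (TRIP-style pools). Extracts reporter
    barcodes from indel-PCR and inverse-PCR sequencing reads, corrects
    barcode sequencing errors by Levenshtein clustering, maps reporter
    integration sites from inverse-PCR alignments with chimera-aware
    soft-clip handling, calls per-read repair scars (indel class and
    size) from spacer displacement or pairwise alignment, and
    quantifies the balance between microhomology-mediated and
    non-homologous end-joining per integration. A full synthetic-data
    simulator generates reporters, mini-genomes, reads, alignments and
    ground truth so every stage can be exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
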