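Package: probeaudit
Title: Structural Audit of Phylogenetic Microarray Probe-Set Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing OTU-to-probe catalogs of 25-mer phylogenetic
    microarrays such as the G2 PhyloChip. Builds an inverted probe index and
    quantifies probe sharing and probe-set uniqueness; detects structurally
    confounded probe sets (exact subsets of other sets, sets assemblable as
    unions of other sets, and non-functional sets that fail to match their own
    reference 16S sequence); simulates in-silico hybridization of a defined
    community by exact 25-mer lookup with fractional presence thresholds; and
    tests probe-set independence with the exact null distribution of Pearson's
    correlation and hypergeometric enrichment. Includes seed-deterministic
    synthetic-data generators with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
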