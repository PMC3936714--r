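Package: oriscope
Title: Replication Origin Usage and Architecture in Multireplicon Archaeal Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying multi-origin DNA replication in haloarchaea.
    Simulates marker-frequency signals from asynchronous exponentially growing
    cell populations replicating circular replicons from one or more origins,
    calls origin peaks from two-channel marker-frequency profiles and fits
    per-origin firing probabilities, scans genome sequence for the
    haloarchaeal origin architecture (inverted origin-recognition-box pairs
    with G-string extensions, AT-rich cores, G-rich inverted-repeat enhancers,
    ORB-rich initiator-titration clusters, and adjacent orc1/cdc6 genes),
    computes GC/AT nucleotide-disparity tracks, and encodes the genetic logic
    of per-replicon origin essentiality, cognate-initiator specificity and
    equilibrium initiator titration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
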