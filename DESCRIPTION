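Package: uceprobe
Title: Ultraconserved-Element Probe Design and In-Silico Sequence Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design hybrid-capture probe (bait) sets for ultraconserved
    elements (UCEs) from soft-masked genome and transcriptome assemblies, and
    evaluate them by in-silico capture. Implements conserved-locus discovery by
    error-free read tiling and mapping under a divergence ceiling with a
    species-occupancy rule; bait tiling with GC and repeat-content filters;
    similarity-based probe deduplication; temporary, master, taxon-subset and
    merged (mixed) probe-set assembly; and capture evaluation with flank
    extraction, probe re-matching, conflict resolution, per-taxon efficiency,
    and occupancy / shared-locus matrices. A seeded synthetic-genome generator
    with planted conserved cores provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
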