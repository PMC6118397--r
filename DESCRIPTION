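Package: ringcat
Title: Detection, Classification and Cataloguing of RING Finger Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric detection and classification of RING finger zinc-binding
    domains in protein sequences, driven by a declarative table of the seven
    RING types (RING-H2, RING-HC, RING-v, RING-C2, RING-D, RING-S/T, RING-G)
    defined by zinc-ligand identities and inter-ligand spacer ranges. Groups
    detected proteins into families versus lone genes by similarity outside
    the RING domain, builds ligand-anchored RING-domain alignments and
    neighbor-joining phylogenies with bootstrap support, profiles intron
    architecture of the underlying genes from GFF3, extracts conserved
    sequence blocks and scans consensus motifs, and summarizes multi-proteome
    surveys. Ships a seeded synthetic-proteome simulator with truth manifests
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
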