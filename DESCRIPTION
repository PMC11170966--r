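Package: sideroscreen
Title: Rule-Based Discovery and Chemical-Space Clustering of Siderophore
    Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens molecule libraries for candidate siderophores
    (microbial iron chelators) with a curated registry of iron-coordinating
    functional-group substructure patterns and veto patterns for chemically
    blocked variants.  Provides canonical-SMILES deduplication and record
    merging, per-molecule element statistics, Tanimoto fingerprint novelty
    assessment against a reference set, and minimum-spanning-tree
    chemical-space clustering against a background natural-product library
    with size-ranked cluster, group, and record (x.y.z) identifiers and
    group-level biosynthetic-type inference.  Includes a download-free
    fixture bed of literature-standard siderophore structures, engineered
    decoys, and veto constructs, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
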