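Package: rrcnet
Title: Residue-Residue Connection Graphs and Feature Engineering for
    Transmembrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs local and global residue-residue connection graphs
    under unipartite and bipartite constraints (square patch, helix-packing
    'memconp' template, cross), assigns correlation-matrix features to the
    realized connections in time linear in the number of residues or residue
    pairs of interest, and computes a cumulative correlation-coefficient
    (cumuCC) score per residue from globally top-ranked pair scores.
    Also provides transmembrane topology parsing and relabeling in a
    PDBTM-style XML dialect, structure-to-sequence residue mapping by global
    alignment, sequence windowing utilities, topology-aware quality-control
    filters, a seeded synthetic-fixture generator, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
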