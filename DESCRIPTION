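Package: spadkit
Title: Substructure-Pair Descriptors for Peptides with Non-Natural Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the substructure-pair descriptor (SPAD) for peptide
    QSAR: peptides built from natural and non-natural amino-acid monomers are
    encoded as binary fingerprints over triples (substructure, intermediate
    binding, substructure), where the intermediate binding is the number of
    residues separating the two substructure carriers. Includes a 49-pattern
    base substructure vocabulary with automatically derived complements,
    entropy- and redundancy-based vocabulary screening, Tanimoto similarity
    ranking against active references, enrichment-factor curves, an
    atom-pair baseline descriptor over the assembled peptide graph, and a
    seeded synthetic benchmark generator (motif-carrying actives plus
    random-sequence decoys). Chemistry is handled through OpenBabel via
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
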