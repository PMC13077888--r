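Package: cpaaiDelimit
Title: Genus Delimitation from Core-Proteome Average Amino Acid Identity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for automated genus-level taxonomic assignment of
    bacterial genome assemblies. Extracts a panel of marker proteins from
    nucleotide assemblies by six-frame translated homology search, builds a
    trimmed concatenated amino-acid supermatrix with all-X placeholders for
    missing markers, computes core-proteome average amino acid identity
    (cpAAI) under pairwise deletion, builds neighbor-joining trees and tests
    monophyly, delimits genera by reconciling a cpAAI threshold with tree
    topology, and applies ANI/dDDH decision rules to flag synonymous species
    names. Includes a calibrated synthetic-data generator so every stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
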