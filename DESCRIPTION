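Package: xlinkRT
Title: Multi-Dimensional Retention Time Prediction and Rescoring for
    Crosslinked Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts multi-dimensional chromatographic retention behaviour
    (reversed-phase retention time plus strong cation exchange and hydrophilic
    strong anion exchange fraction numbers) of crosslinked peptide pairs with a
    Siamese multi-task recurrent neural network, and uses the predictions to
    rescore crosslink spectrum matches (CSMs) with a semi-supervised linear
    support vector machine. Includes target-decoy plus entrapment false
    discovery rate estimation with decoy-decoy correction and roll-up to
    peptide-pair, residue-pair and protein-protein interaction levels, an
    entrapment database builder with greedy nearest-neighbour protein matching,
    and a fully seeded synthetic-data generator so the whole workflow is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
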