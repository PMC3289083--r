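Package: ATPbindR
Title: Sequence-Based Prediction of ATP-Binding Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting ATP-binding residues from protein sequence.
    Generates per-residue binding labels from protein-ligand complexes (3.9 Angstrom
    non-hydrogen contact rule), encodes residues with a sliding-window feature
    representation over evolutionary profiles (PSSM), predicted secondary structure,
    solvent accessibility, dihedral angles, amino-acid groups, conservation scores
    and collocated amino-acid pairs, ranks features by point-biserial correlation,
    performs best-first forward selection and SVM kernel/cost parameterization under
    chain-level cross-validation, calibrates an MCC-maximizing binarization threshold,
    and evaluates predictions with per-residue and per-sequence ROC/MCC statistics.
    Includes alignment-transfer and conservation baselines, a max-probability
    disjunction consensus, and a synthetic-data generator with planted signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
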