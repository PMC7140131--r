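Package: ihrc
Title: Interhelical Residue Contact Prediction for Alpha-Helical Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of interhelical residue contacts in
    alpha-helical transmembrane proteins. Computes evolutionary covariation
    between alignment columns by three correlated-mutation statistics (ELSC,
    mutual information, OMES), per-residue conservation from position-specific
    scoring matrices, digitized membrane topology and within-helix relative
    position tracks, and assembles 31-element residue-pair feature vectors via
    dual sliding windows. Ground-truth contacts are labeled from atomic
    coordinates under three distance definitions. A small one-dimensional
    convolutional network classifies candidate pairs, with protein-level
    cross-validation and MCC-based evaluation. A synthetic-data module
    generates alignments with planted coevolving column pairs and idealized
    helix-bundle coordinates so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
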