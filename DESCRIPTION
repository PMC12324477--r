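Package: clfootprint
Title: Covalent-Labeling Footprinting Analysis for Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for carboxyl-group (glycine ethyl ester)
    covalent-labeling mass-spectrometry footprinting of protein complexes.
    Rolls peptide-level modified/unmodified intensities up to residue-level
    modification fractions, computes bound-minus-unbound differential surface
    exposure, projects exposure changes onto structure models (windowed
    profiles, paralog remapping, B-factor export with clipping), calls merged
    sites of exposure change, classifies cross-condition overlaps, summarises
    gains and losses by complex module, and aggregates peptide-tiling contact
    probabilities to map short-linear-motif residues onto a receptor pocket.
    A synthetic-data generator produces digests, labeling intensities and
    contact matrices with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
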