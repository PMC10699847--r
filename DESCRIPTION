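Package: foldeval
Title: Loss Functions and Assessment Statistics for Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-level loss functions and model-quality statistics for
    protein structure prediction, computable on real or synthetic structures
    without any neural network. Implements a sequentially conditioned
    side-chain torsion-angle loss, the frame-aligned point error (FAPE) with
    distogram-derived pair weighting, cross-entropy losses for 8-state
    secondary structure and binned side-chain confidence, and their weighted
    combination. Evaluation utilities cover chi-angle accuracy at a fixed
    degree criterion, per-sequence side-chain confidence, a contact-based
    template alignment-quality ratio, and CASP-style Z-score aggregation with
    the assessor weighting over eleven metrics. Includes deterministic
    synthetic peptide generators for testing, readers for PDB structures,
    pairwise alignments, distograms and metric tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
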