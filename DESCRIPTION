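Package: rnarefine
Title: Restrained Energy Refinement of Nucleic Acid Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fine-grained refinement of RNA and DNA 3D structure models by
    restrained energy minimization. Implements an AMBER-family molecular
    mechanics energy with analytic gradients, extended by four optional
    restraint terms: explicit hydrogen bonds, base-pair co-planarity,
    knowledge-based backbone regularization against a conformer library,
    and custom harmonic springs. Includes PDB input/output with atom-name
    normalization and hydrogen completion, Watson-Crick base-pair
    detection or imposition from dot-bracket secondary structure,
    steepest-descent and Polak-Ribiere conjugate-gradient minimizers with
    golden-section line search, structure quality metrics (superposed
    RMSD, interaction network fidelity, clash score) and generators for
    ideal A-form duplexes and controlled decoy sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, graphics, grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, bio3d, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
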