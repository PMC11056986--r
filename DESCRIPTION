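Package: trajdiverge
Title: Per-Residue Divergence Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares pairs of (coarse-grained) molecular dynamics
    trajectories residue by residue using the symmetrized Kullback-Leibler
    divergence between discretized positional distributions, including a
    moving-window time-resolved variant with global normalization.
    Provides weighted Kabsch superposition with iterative
    variance-reweighted alignment, RMSD and center-of-mass distance
    series, Shrake-Rupley solvent accessible surface area with a
    coarse-grained probe, readers for GRO/PDB/DCD and a plain-text
    fixture format, and a generator of synthetic bead-per-residue
    trajectory pairs with planted conformational changes for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, bio3d, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
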