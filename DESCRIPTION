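Package: enmspm
Title: Elastic Network Normal Modes and Structural Perturbation Analysis of Chaperone Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Coarse-grained anisotropic elastic network models for protein
    assemblies at carbon-alpha resolution. Builds harmonic contact networks
    from PDB structures, computes normal modes, measures the overlap of each
    mode with an observed conformational transition, derives per-mode residue
    cross-correlation (covariance) maps and relative displacement profiles,
    and locates allosteric hot-spot residues with the structural perturbation
    method. Includes Kabsch superposition, symmetric-complex assembly by
    least-RMSD overlay, cutoff calibration against experimental B-factors,
    deterministic synthetic-structure generators (bead chains, hinged
    two-domain toys, dimer/cochaperone assemblies) with known ground-truth
    dynamics, and a config-driven analysis pipeline that writes a complete
    report bundle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
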