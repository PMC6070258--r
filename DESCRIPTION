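Package: mdscope
Title: Multi-Scale Analysis of Protein Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the hierarchy of motions in molecular dynamics
    trajectories of multi-domain proteins: least-squares superposition and RMSD
    profiles, per-residue fluctuations and B-factors, essential dynamics (PCA)
    with Kullback-Leibler convergence diagnostics, anisotropic elastic-network
    normal modes, dynamical cross-correlation maps, per-residue Morlet continuous
    wavelet maps with significance testing, kernel-density free-energy landscapes
    with basin extraction, hinge detection from backbone dihedral deviations, and
    hydrogen-bond occurrence maps. Includes synthetic-trajectory generators with
    planted, recoverable structure so every analysis stage can be validated
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
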