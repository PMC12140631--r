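Package: spectre
Title: Volumetric EEG Potential Reconstruction Constrained by Tissue
    Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward and inverse modeling of weakly evanescent brain waves
    for electroencephalography (EEG). Implements the anisotropic,
    inhomogeneous wave equation for the electric-field potential that
    follows from retaining the displacement current in Maxwell's
    equations, its closed-form dispersion analytics, a pseudo-spectral
    time-domain forward solver on voxelized tissue grids, a
    frequency-domain iterative inverse solver that reconstructs
    band-limited volumetric potentials from surface electrode recordings,
    and an entropy-based spatiotemporal mode decomposition of the
    reconstructed 4D fields. Includes layered-sphere phantoms, synthetic
    source and sensor simulation with known ground truth, and readers and
    writers for NIfTI volumes, EDF/CSV recordings, and electrode tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
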