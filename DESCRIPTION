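Package: nmrcell
Title: Magnetostatic Modelling and Susceptometry for NMR Sample Microcells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of static-field (B0) inhomogeneity in NMR
    sample cells and the susceptometry calculus built on it. Builds
    constructive-solid-geometry scenes of sample geometries (Shigemi tube,
    resin plug in a tube, 3D-printed ellipsoidal microcell with access
    channel), voxelizes them onto regular grids, computes the nuclear
    (Lorentz-corrected) resonance-offset field with an FFT dipole-kernel
    solver backed by a brute-force summation oracle and closed forms
    (planar-interface limit, ellipsoid demagnetizing factors), simulates
    solvent line shapes under coil-sensitivity and slice-selection
    weighting, extracts volume magnetic susceptibilities from
    slice-selected interface shifts, models the NaCl and paramagnetic
    doping dependence of solvent and resin susceptibility, and exports
    printable cell geometries as binary STL meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
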