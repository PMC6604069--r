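Package: aquafrac
Title: Fractal Analysis of Water Dynamics from GHz Dielectric Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing water structure in aqueous and
    biological materials from the GHz dielectric relaxation of the
    hydrogen-bonding network. Provides forward evaluation and nonlinear
    least-squares fitting of Havriliak-Negami family relaxation spectra
    (Debye, Cole-Cole, Cole-Davidson special cases), extraction of the
    fractal dimension of water structures from tau-beta trajectories via
    the Ryabov relation with solution/dispersion classification,
    scale-aware box-counting fractal dimension estimation on binary
    images and voxel grids with two-regime breakpoint detection, and a
    simplified axisymmetric electrostatic model of open-ended coaxial
    probe electrodes with penetration-depth estimation (single
    exponential fit and the 54-percent-of-surface-potential criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
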