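Package: wavemra
Title: Wave-Encoded Time-of-Flight MR Angiography Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for wave-encoded 3D
    time-of-flight magnetic resonance angiography. Synthesizes sinusoidal
    wave-encoding gradients and their zeroth/first-order moments, builds the
    corkscrew k-space trajectory and its projection-based calibration,
    generates 2D-CAIPIRINHA and variable-density Poisson-disc undersampling
    masks, implements the point-spread-function encoding forward model in
    hybrid k-space with LSQR (wave-CAIPI / 2D-CAIPI) and nonlinear conjugate
    gradient compressed-sensing (CS-wave / CS) reconstructions, and evaluates
    results with pseudo-replica g-factor maps, contrast-to-background ratio,
    standard and vessel-masked structural similarity, and maximum intensity
    projections. Includes a digital vessel phantom generator with multi-coil
    acquisition simulation and gradient first-moment flow-ghosting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    png,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
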