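Package: cryotwin
Title: A Digital Twin for Cryo-Electron Tomography Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital twin of a cryo-electron tomography
    experiment. Builds virtual frozen-hydrated specimens (planar lamellae or
    cylinders containing macromolecular particles embedded in amorphous ice),
    simulates physically motivated transmission electron microscope tilt
    series (multislice wave propagation, dose-dependent beam damage, contrast
    transfer function with coherence envelopes, detector quantum efficiency
    and Poisson counting noise), reconstructs them by weighted back
    projection with per-particle contrast-transfer correction and
    wedge-masked subtomogram averaging, and scores the reconstructions
    against the known ground truth with Fourier shell correlation. Closing
    the loop in software allows in-silico optimisation of acquisition
    parameters such as tilt range, tilt increment and sample geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
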