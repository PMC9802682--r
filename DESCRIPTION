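Package: psoct
Title: Simulation and Depth-Resolved Reconstruction for Catheter-Based
    Polarization-Sensitive Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for polarization-sensitive optical coherence tomography
    (PSOCT) polarimetry with benchtop raster and endoscopic helical (rotating
    fiber probe) scan geometries. Provides exact SU(2)/SO(3) retarder algebra,
    ground-truth birefringent tissue phantoms (layered slabs and white-matter
    tract-like structures), a forward measurement model with two
    Stokes-orthogonal input polarization states, spectral binning, system and
    catheter polarization distortions, speckle and additive noise, and the
    matching reconstruction pipeline: rotation estimation, symmetrization to
    linear-eigenstate form, ball-lens catheter compensation, iterative layer
    peeling into depth-resolved local birefringence and optic-axis
    orientation, degree-of-polarization masking, axis referencing, and
    composite hue/brightness rendering with en-face, cross-sectional,
    rotational, unwrapped and tangential views.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
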