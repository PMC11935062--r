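Package: depthPSF
Title: Axial Resolution and Attenuation Modeling for Confocal
    Through-Plane Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the axial resolution of a confocal microscope, its
    decay with focus depth, and the Beer-Lambert attenuation coefficient
    of a translucent layered sample from a single confocal through-plane
    scan. The measured depth profile is modeled as the convolution of a
    Lorentzian axial point spread function, whose full width at half
    maximum grows linearly between the layer interfaces, with a
    rectangular composition profile carrying an exponential intensity
    decay. Interfaces are located by sigmoid fits at inflection points of
    the profile; the four physical parameters are optimized by a
    coarse-to-fine grid sweep of the residual sum of squares. Supports
    hyperspectral depth scans (sum-filter band integration), single- and
    multilayer specimens, objective calibration on optically thin
    samples, and a synthetic-scan generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'depthPSF-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'spectral-io.R'
    'interface-detection.R'
    'psf-model.R'
    'forward-model.R'
    'sweep-fitter.R'
    'multilayer.R'
    'synthetic-data.R'
    'cli.R'
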