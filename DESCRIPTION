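Package: sofisect
Title: Super-Resolution Optical Fluctuation Imaging with Temporal-Focusing
    Two-Photon Excitation: Simulation and Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for super-resolution optical fluctuation imaging (SOFI)
    under temporal-focusing (TF) two-photon excitation. Provides a physically
    motivated simulator of blinking-emitter movies (two-state Markov
    photoswitching, separable Gaussian detection point spread function,
    TF axial excitation profile, Poisson shot noise plus camera read noise
    with a photon-number-resolving dynamic-range clamp), per-pixel temporal
    cumulant images of orders 2 and 3 with a fluctuation-versus-bleaching
    diagnostic, and the quantification chain: region-averaged sectioning
    curves versus defocus, axial-response and Gaussian curve fitting with
    FWHM extraction, and emitter-wise lateral PSF FWHM statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'optics.R'
    'blinksim.R'
    'quantify.R'
    'sofi.R'
    'io.R'
    'config.R'
    'cli.R'
    'sofisect-package.R'
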