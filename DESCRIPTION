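Package: tomopipe
Title: Subtomogram Averaging and Model Fitting for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of the cryo-electron
    tomography workflow used to solve membrane-bound ribosome-translocon
    structures in situ: simulation of vesicle scenes and tilt series with CTF
    and dose-dependent noise, frame alignment, strip-based defocus estimation
    and phase flipping, marker-based tilt-series alignment, weighted
    backprojection, missing-wedge-aware six-dimensional template matching,
    constrained principal component classification, conventional and
    gold-standard iterative subtomogram averaging with Fourier shell
    correlation resolution estimation, local resolution, B-factor sharpening,
    and atomic-model fitting (rigid, domain-wise, helix-axis scan, elastic
    flexible refinement) with screw-axis decomposition of conformational
    changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
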