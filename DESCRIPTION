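Package: valvescan
Title: Multi-Scale X-Ray Diffraction and Video-Extensometry Analysis of
    Heart-Valve Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-scale characterisation of mitral and tricuspid
    valve strips spanning papillary muscle, chordae tendinae and leaflet.
    Reduces scanning fiber X-ray diffraction images to calibrated radial and
    azimuthal profiles, fits collagen meridional and muscle equatorial
    reflections to obtain D-periods, d-spacings, relative composition and
    fiber-orientation ellipses, and assembles composition profiles,
    molecular-strain heatmaps and strain-per-thickness failure predictors.
    Couples these to video-extensometry mechanics: fiducial-marker tracking,
    regional stress-strain curves, toe and linear moduli, ultimate stress and
    failure localisation. A synthetic valve-strip phantom renders diffraction
    frames, load-displacement traces and marker video with known ground truth
    so the full pipeline can be exercised and validated without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    zoo,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
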