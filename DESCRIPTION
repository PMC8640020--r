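Package: wfpi
Title: Wavefront Phase Imaging of the Eye from Two Defocused Intensity Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers high-resolution ocular wavefront phase maps from a pair of
    intensity images captured in two planes around the conjugated pupil plane.
    Phase gradients are estimated by directional cumulative-profile matching
    (one-dimensional transport along families of lines at many orientations),
    scaled to physical units, and integrated by Fourier-domain least squares
    over an arbitrary pupil mask. Includes OSA-standard Zernike decomposition
    (66 terms), band RMS statistics, sphero-cylindrical refraction conversion,
    largest-inscribed-pupil geometry, a geometric-optics forward simulator
    (defocus and trial-cylinder series, deformable-mirror style random Zernike
    surfaces, fine peak-and-valley textures, photon/read noise), and in-silico
    calibration and validation experiment harnesses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
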