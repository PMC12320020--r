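Package: vhdot
Title: Simulation and Analysis Pipeline for Very High-Density Diffuse Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and benchmarking very high-density diffuse
    optical tomography (VHD-DOT) imaging arrays and for analysing the channel
    data they produce. Builds checkerboard source/detector lattices at
    arbitrary pitch, computes analytic semi-infinite-slab sensitivity
    (Jacobian) matrices from the continuous-wave photon-diffusion Green's
    function, reconstructs absorption images with Tikhonov plus
    spatially-variant regularization, converts two-wavelength absorption to
    oxy-/deoxy-haemoglobin via the extinction-coefficient matrix, and scores
    array designs with point-spread-function image-quality metrics (FWHM,
    localization error, effective resolution, SNR) versus depth. Also
    implements the measurement-space preprocessing chain (log-mean ratios,
    noisy-channel rejection, band-pass filtering, superficial signal
    regression, downsampling), GLM task mapping with fixed-effects group
    statistics and Dice overlap, spatiotemporal template-matching decoding of
    block-design and movie-style stimuli, naturalistic feature regressors, and
    a synthetic two-wavelength session generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
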