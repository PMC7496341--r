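Package: MARbench
Title: Task-Based Assessment of CT Metal Artifact Reduction Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A simulation framework for objective, task-based assessment of
    computed-tomography metal artifact reduction (MAR) algorithms. Builds a
    numerical head phantom with iron implants and a rotatable lumpy-background
    inset, simulates noisy polychromatic parallel-beam projection data with
    beam hardening, constant scatter, Poisson counting noise and Gaussian
    readout noise, reconstructs with filtered backprojection and two
    sinogram-inpainting MAR variants (sinogram-domain and image-domain metal
    segmentation), and quantifies low-contrast detectability with a
    channelized Hotelling observer using dense difference-of-Gaussians
    channels. Resubstitution and hold-out AUC learning curves ("antler plots")
    are extrapolated to infinite training size with bias and variance
    uncertainty, yielding detectability curves over signal amplitude and dose.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
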