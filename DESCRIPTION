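Package: nbcm
Title: Contrast-Normalized BCM Plasticity and V1 Receptive-Field Development
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the development of primary-visual-cortex (V1)
    simple-cell receptive fields under the Bienenstock-Cooper-Munro (BCM)
    synaptic plasticity rule and its contrast-normalized variant (NBCM), in
    which divisive normalization couples an otherwise independent population
    of model neurons.  Provides a retinal difference-of-Gaussians front end
    that turns natural (or synthetic 1/f) images into standardized model
    retinal-ganglion-cell response patches, a compiled training loop with a
    sliding modification threshold and annealed learning rate, Fourier-domain
    reconstruction of stimulus-space receptive fields with spatial-frequency
    and orientation tuning estimation, and a suite of population-coding
    quality metrics (lifetime and population sparseness, dispersal,
    orthogonality, matrix rank, and sinusoid-reconstruction coverage) for
    comparing the codes the two rules learn.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
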