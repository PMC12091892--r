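Package: suppfilt
Title: Filter-Based Models of Excitation and Suppression in Retinal
    Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and evaluates filter-based Poisson encoding models of
    retinal ganglion cell spiking in a unified structure: a
    linear-nonlinear (LN) cascade and three extensions with subtractive,
    divisive, or spike-history-feedback suppression.  Provides stimulus
    generators (Gaussian white-noise flicker with frozen-noise repeats,
    chirp stimuli with frequency and contrast sweeps), spike-triggered
    average and covariance analysis, constrained block-coordinate
    maximum-likelihood training with shape-constrained tent-basis
    nonlinearities, evaluation metrics (information per spike, Poisson
    explained variance, sliding-window R squared), cell-characterisation
    procedures (transiency, ON-OFF detection, unit selection, duplicate
    removal), and a synthetic ground-truth cell factory for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
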