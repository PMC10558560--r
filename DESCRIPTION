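Package: stocot
Title: Stochastic Co-Teaching for Training with Unknown Levels of Label Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training procedures that are robust to label noise without
    requiring the noise rate to be known. Implements stochastic co-teaching,
    in which two independently initialized learners each select training
    units for the other by comparing the posterior probability of the
    recorded label against a threshold drawn from a beta distribution, with
    clamping, a linear ramp-in schedule, and mini-batch stability
    safeguards. Includes conventional co-teaching (fixed forget rate) and
    standard-training baselines, bias and uniform label-noise transition
    matrices with exact-count corruption, a rejection-rate-based estimator
    of the label-noise rate, adapters for single-label, multi-label and
    dense (pixel-wise) classification with tiled threshold fields, synthetic
    ring-of-Gaussians and cardiac-like segmentation data generators, small
    reference learners, and segmentation overlap/distance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    png,
    yaml,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
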