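Package: mammofuse
Title: Deep Fusion Learning for Mammographic Region-of-Interest
    Classification
Version: 0.1.0
Authors@R:
    person("Mammofuse", "Developers", email = "maintainer@mammofuse.org",
           role = c("aut", "cre"))
Description: A two-stage framework for computer-aided diagnosis on
    MIAS-style mammograms.  Images are denoised with a median filter,
    enhanced with contrast-limited adaptive histogram equalization
    (CLAHE), and 120x120 regions of interest (ROIs) are extracted around
    annotated abnormalities (or random breast locations for normals).
    Multi-branch fusion heads -- per-block global-average-pooling
    concatenation, or a 1x1-convolution channel bottleneck per branch --
    are trained on randomly sampled 72x72 patches over a frozen
    convolutional backbone, and each ROI is classified by majority
    voting over 25 patch predictions.  Includes a synthetic phantom
    generator emitting MIAS-format datasets so the entire pipeline runs
    with no download, and full evaluation (per-class recall, precision,
    F1, accuracy, ROC and precision-recall curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
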