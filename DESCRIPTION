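Package: histobridge
Title: Omics-Conditioned Diffusion Bridges for Histopathology Image
    Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-domain, multi-omics translation of histopathology
    image patches with conditional denoising-diffusion bridges. A U-Net
    noise predictor is conditioned on a categorical domain label, a
    per-gene binary mutation profile and a per-gene quantile-normalized
    expression profile; deterministic DDIM solves encode an image to its
    diffusion latent under the source condition and decode it under the
    target condition, translating or counterfactually editing the image.
    Includes the surrounding tool chain: slide tissue masking and patch
    tiling, stain deconvolution (DAB positivity), a Frechet-distance and
    SSIM evaluation suite with pluggable feature extractors, isolation
    forest inlier scoring, retrieval metrics, a reduced-timestep solver
    calibration procedure, and a synthetic-data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
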