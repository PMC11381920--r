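Package: dvquant
Title: Quantification of Dorsoventral Morphogen Gradients and Nascent
    Transcription in Embryo Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative analysis of two-channel confocal
    cross-sections of blastoderm-stage Drosophila embryos: embryo outline
    detection and unrolling of the nuclear layer to a rectangular strip,
    marker-based watershed segmentation of nuclei with per-compartment
    Otsu thresholding, Gaussian fitting of dorsoventral intensity
    gradients with session/time-course/DV-axis normalization,
    width-rescaled multi-embryo gradient averaging, nascent-transcript
    spot calling in z-stack time courses with a percentile score, and
    penalized expression-domain boundary estimation. Ships a synthetic
    embryo-image generator with complete ground truth so that every
    pipeline stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    digest,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
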