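Package: txspot
Title: Quantitative Analysis of Live-Cell Transcription Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of live-cell transcription reporter
    imaging at single gene loci: sub-pixel fluorescent spot detection and
    Gaussian localization, ON/OFF transcription-state calling from relative
    spot intensities and regulatory-factor proximity, locus mobility
    statistics (mean square change in distance and mean squared displacement
    with anomalous-diffusion fitting), FRAP recovery-curve fitting with joint
    baseline estimation, cross-correlation analysis of dual
    (TSS-proximal/3'UTR) nascent-RNA reporters for elongation kinetics,
    nearest regulatory-factor cluster distance analysis, single-molecule FISH
    quantification and ChIP-qPCR percent-input calculations. A synthetic
    microscopy generator (telegraph-model bursting, fractional-Gaussian locus
    diffusion, PSF-rendered spot images with Poisson-Gaussian camera noise)
    provides ground-truthed inputs so every stage of the pipeline is testable
    without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
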