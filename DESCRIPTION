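Package: qhcr
Title: Quantitative Analysis and Simulation of HCR Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level relative quantitation for hybridization chain
    reaction (HCR) immunohistochemistry and RNA in situ hybridization
    imaging (qHCR imaging): subcellular voxel binning and normalization,
    two-channel accuracy/precision analysis by orthogonal (total least
    squares) regression, read-out/read-in gating between anatomical and
    expression space, signal-to-background decomposition into
    autofluorescence, nonspecific detection and nonspecific amplification
    components, and HCR amplification-gain (polymer length) estimation
    from paired versus h1-only hairpin experiments. Includes a synthetic
    multichannel fluorescence image generator with known ground truth that
    emulates HCR signal physics (probe binding, geometric polymer growth,
    background components, PSF blur, shot and read noise), so every
    analysis stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
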