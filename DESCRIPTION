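Package: nirphantom
Title: Simulation and Sensitivity Metrics for NIR Fluorescence Tumor Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying near-infrared fluorescence images of
    tissue-mimicking tumor phantoms, as used to characterize
    fluorescence-guided surgery imaging systems. Provides a synthetic
    phantom-image generator with known ground truth (diffusion-theory depth
    attenuation, illumination inhomogeneity, Poisson/Gaussian sensor noise,
    per-system quantization), loaders that bring heterogeneous system output
    (16-bit grayscale TIFF, 8-bit RGB PNG) onto a common normalized scale,
    two region-definition strategies (Otsu-derived intensity bands and
    fixed-diameter circular regions of interest at the intensity peak), the
    four sensitivity metrics SBR, SNR, CNR and CVR, and study-level
    aggregation across replicates, fluorophore concentrations and ROI sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
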