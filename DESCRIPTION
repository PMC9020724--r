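Package: specphos
Title: Hyperspectral Phenotyping and Association Analysis of Leaf Phosphorus Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating leaf inorganic phosphate (Pi) status in rice
    from visible/near-infrared reflectance spectra (420-790 nm), and for
    post-processing genome-wide association results on spectral traits.
    Includes screening of NIR/VIS reflectance-ratio indices against Pi
    content, constrained exponential-decay calibration of reflectance ratios
    against Pi, a multi-task one-dimensional convolutional network that
    classifies phosphorus-deficiency level and predicts log10 Pi with an
    auxiliary spectral-reconstruction objective, Grad-CAM attribution over
    wavelengths, Bonferroni-based locus calling with linkage-disequilibrium
    candidate windows, and a synthetic-panel generator reproducing the
    statistical structure of a 172-accession hydroponic phosphorus trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
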