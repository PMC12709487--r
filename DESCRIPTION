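Package: fractIPR
Title: Fractal, Multifractal and Light-Localization Metrics for Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiparametric characterization of brightfield microscopy
    images of tissue. Computes sub-box box-counting fractal dimension maps
    with length-scale and threshold sweeps, logarithmic and functional
    transforms of the fractal dimension with histogram, polynomial and
    Gaussian distribution summaries, Chhabra-Jensen multifractal f(alpha)
    spectra, and inverse-participation-ratio (IPR) statistics of
    tight-binding Hamiltonians built from intensity-derived optical
    potentials. Includes generators for synthetic images with analytically
    known fractal dimension, multifractal spectrum and disorder strength
    (Sierpinski carpets, randomized multiplicative cascades, correlated
    Gaussian disorder fields) and a two-cohort study simulator, plus
    control-versus-disease group comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    EBImage,
    minpack.lm,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
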