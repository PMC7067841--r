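Package: memlipid
Title: Membrane Lipidome Homeostasis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for studies of mammalian membrane
    lipidomic and biophysical homeostasis. Parses shotgun-lipidomics species
    nomenclature (sum-composition and chain-resolved), computes lipidome
    composition statistics (mol% normalization, unsaturation indices,
    exclusion-set "remaining lipid" analyses, saturation profiles, omega-3 and
    omega-6 chain fractions, class composition, fold changes), fits first-order
    kinetic models to fatty-acid incorporation and wash-out time courses,
    computes C-Laurdan generalized polarization (GP) from emission spectra and
    two-channel spectral images (binning, background subtraction, dual-channel
    thresholding, region quantification), and estimates plasma-membrane
    permeability to fluorescein diacetate from fluorescence traces via Fick's
    law. Includes seed-deterministic synthetic-data generators with retained
    ground truth for every input type, and a study-level pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
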