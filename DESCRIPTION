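Package: morphodyn
Title: Morphodynamic Single-Cell Phenotyping from Microwell Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of microwell time-lapse fluorescence
    imaging of rotating single cells. Generates synthetic microwell scenes
    with known ground truth (occupancy, phenotype, sub-phenotype, viability),
    segments and filters live single cells, extracts a fixed 169-column
    morphology feature vector per cell and timepoint (shape, Zernike moment
    magnitudes, Haralick texture, intensity), classifies phenotypes with a
    leakage-free normalise/PCA/AdaBoost pipeline under repeated shuffled
    holdout (including rare-subpopulation imbalance sweeps), and discovers
    morphological sub-phenotypes with homogeneity-constrained k-means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
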