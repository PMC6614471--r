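Package: specfuse
Title: Fusion and Chemometric Analysis of FTIR and LA-ICP-MS Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Merges Fourier-transform infrared (FTIR) hyperspectral images and
    laser-ablation ICP-MS elemental maps of tissue sections into one
    co-registered, co-normalized dataset. Provides the five-step FTIR spectral
    correction chain (water-vapor subtraction, CO2 removal, amide-area scaling,
    piecewise-linear baseline subtraction, signal-to-noise filtering),
    elemental-image background subtraction, standardization, padding and
    stitching, rotation/binning/Fourier-crop co-registration, feature fusion
    with element replication, and downstream chemometrics (Pearson correlation
    mapping, PCA, hierarchical and K-means double clustering). Includes a
    synthetic paired-scene generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, graphics, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io-envi.R'
    'io.R'
    'ftir-preprocess.R'
    'la-preprocess.R'
    'register.R'
    'fusion.R'
    'chemometrics.R'
    'synthetic.R'
    'pipeline.R'
    'specfuse-package.R'
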