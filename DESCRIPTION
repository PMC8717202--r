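Package: prrtdosim
Title: Voxel Dosimetry and Radiobiologic Modeling of Lu-177 Peptide
    Receptor Radionuclide Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for preclinical Lu-177-DOTATATE dosimetry and
    radiobiology. Generates synthetic receptor-driven tissue phantoms and
    activity maps, computes voxel absorbed-dose and dose-rate maps by
    dose-point-kernel convolution with a packaged Lu-177 electron kernel,
    derives region S values, dose-volume histograms and generalized
    equivalent uniform dose, fits biexponential dose-rate kinetics, models
    in vivo cell survival with the linear-quadratic model including the
    Lea-Catcheside protraction factor and repopulation, fits DNA-damage
    repair and tumor regrowth curves, and correlates absorbed dose with
    double-strand-break induction including chi-square template matching of
    expression patterns.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    EBImage,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
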