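Package: lungstrain
Title: Regional Volumetric Lung Strain Analysis from Paired CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies global and regional volumetric lung strain from paired
    thoracic CT volumes acquired at two ventilation states (end-expiration and
    end-inspiration, with and without positive end-expiratory pressure).
    Provides Hounsfield-threshold lung segmentation, free-form-deformation
    B-spline image registration, Jacobian-based volumetric strain recovery on a
    finite-element mesh, CT aeration-compartment mapping, volume-preserving
    10x10 region-of-interest partitions with paired regional statistics, and
    Bohr dead-space computation from volumetric capnography. Includes a
    synthetic phantom generator with analytically known deformations so every
    stage can be validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
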