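Package: qlus
Title: Quantitative Lung Ultrasound Texture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-assisted analysis of the pleural and subpleural region
    of neonatal lung ultrasound images. Reads monochrome frames (8-bit PNG or
    uncompressed DICOM), rasterises a pleural region of interest bounded by
    the pleural line, rib shadows and a fixed depth, and computes the mean
    grey value together with five grey-level co-occurrence matrix (GLCM)
    texture features (angular second moment, contrast, correlation, inverse
    difference moment, entropy). Zone-level features are averaged into one
    Q-LUS value per infant and correlated, via Spearman's rank correlation
    with bootstrap or Fisher-z confidence intervals, against the oxygen
    saturation index (OSI) and the SpO2/FiO2 ratio, overall and by ultrasound
    machine. A synthetic speckle-image cohort generator with a known latent
    aeration level linking echogenicity to oxygenation makes the full
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    tibble,
    ggplot2,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
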