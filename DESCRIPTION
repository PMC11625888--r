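Package: zfeye
Title: Ocular Phenotyping Pipeline for Zebrafish Myopia Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline for the bespoke computations used to
    phenotype zebrafish models of myopia: the optomotor index (OMI) from
    tracked angular swim trajectories, log-Gaussian spatial-frequency
    tuning-curve fits with omnibus and nested extra-sum-of-squares F-tests,
    ocular biometry and Matthiessen's ratio (retina-to-lens radius) from OCT
    axial landmarks, electroretinogram a-/b-wave feature extraction,
    inner-retinal layer intensity-profile quantification, and relative gene
    expression by the 2^-ddCt method. A seeded synthetic-data module
    generates every input modality with known ground truth so the whole
    pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
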