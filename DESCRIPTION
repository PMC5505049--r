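Package: pulmotex
Title: Grey-Level Co-Occurrence Texture Analysis of Pulmonary CT with
    Grouped Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative texture analysis of lung CT slices for
    computer-assisted detection of pulmonary thromboembolism and other
    parenchymal disease. Segments pulmonary parenchyma by Hounsfield-unit
    windowing, computes masked grey-level co-occurrence matrices in four
    orientations, derives a 22-feature Haralick bank per orientation, and
    classifies slices with one-vs-rest PLS-DA and Gaussian-kernel SVM under
    leave-one-dog-out cross-validation, with ROC analysis and a bootstrap
    test for group mean differences. Includes a synthetic CT-slice study
    generator so the whole pipeline is testable without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
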