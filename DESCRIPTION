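Package: wormquant
Title: Image Quantification and Cohort Statistics for C. elegans
    Microscopy Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of the bespoke image
    quantification used in C. elegans aging studies: lifetime-gated
    autofluorescence unmixing and ratiometric quantification of the HyPer
    hydrogen-peroxide biosensor, mitochondrial-network percent-area
    morphometry from maximum-intensity projections, Oil Red O fat
    densitometry with pseudo flat-field correction, and the cohort
    statistics (Bonferroni-corrected t-tests and ANOVA, Wilcoxon rank-sum
    lifespan comparisons, survival summaries) used to compare treatment
    groups. A synthetic-scene generator with known ground truth makes
    every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    flexsurv,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
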