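Package: maculaquant
Title: Macular Layer Thickness and Capillary Density Quantification from
    OCT and OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the macular inner retina from structural optical
    coherence tomography (OCT) and en face OCT angiography (OCT-A).
    Implements nine-boundary intra-retinal layer segmentation by
    gradient-cost shortest-path search with axial-length magnification
    correction, regional thickness mapping on a fovea-centered grid, and a
    retinal capillary density (RCD) pipeline for en face angiograms:
    bicubic upsampling, foveal avascular zone detection by a Canny-seeded
    level set, noise-floor global thresholding, adaptive thresholding,
    large-vessel subtraction, and annular/sector regional densities.
    Cohort-level tools provide eye-clustered group comparisons, Pearson
    correlations, empirical and binormal ROC/AUC, and logistic composite
    indices. Seeded phantom and cohort generators supply ground-truth
    inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    png,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
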