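Package: choroidmetrics
Title: Quantitative Morphometry of Choroidal Vessels in En Face OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the large vessels of Haller's layer on en face
    optical coherence tomography slab images. Segments the dark vessel
    phase by local-mean thresholding, thins it to one-pixel centerlines,
    and reports vessel area (mm^2), vessel length (mm), and mean vessel
    diameter (mm), together with a symmetry index describing how closely
    the vessel running pattern mirrors about the horizontal fovea line.
    Includes a seeded synthetic generator for vessel-network scenes and
    per-eye metric cohorts, and the cohort-level statistical layer
    (rank-sum group comparisons, chi-square, Spearman correlation, and
    ROC analysis with a Youden-index cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
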