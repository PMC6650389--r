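Package: morphoscreen
Title: Time-Resolved Morphological Screening of Bacterial Antibiotic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for high-throughput, time-resolved
    morphological screening of bacterial populations imaged by phase-contrast
    microscopy. Provides a synthetic-data generator with ground truth,
    single-cell segmentation (contrast enhancement, permissive binarization and
    shape-criteria pruning), a 54-descriptor feature extractor (shape, Fourier
    contour harmonics, intensity and microenvironment blocks), supervised
    classification of cells as lysed or intact (PLS-DA) and into morphological
    classes with a rejection category (SIMCA), 18-dimensional per-strain
    phenotypic profiling with per-plate batch correction and well-level QC,
    detection of strains with atypical antibiotic-response dynamics via
    Hotelling's T2 and squared prediction error against a wild-type PCA
    reference, and downstream k-means clustering with silhouette-based model
    selection and Fisher's exact functional-category enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    cluster,
    tibble,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
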