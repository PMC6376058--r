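Package: radstab
Title: Reproducibility-Driven Radiomics Feature Selection for Multi-Sequence MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the stability of two-dimensional radiomics
    features across repeated manual delineations on multi-sequence MRI.
    Implements an 85-feature extractor (shape, first-order, GLCM, GLRLM,
    GLSZM and NGTDM families) with absolute grey-level discretization,
    reproducibility-based feature selection using two-way mixed intraclass
    correlation (absolute agreement, average measures) and Lin's concordance
    correlation coefficient, redundancy reduction by hierarchical clustering
    on Spearman correlation distance (per sequence and pooled), threshold
    sensitivity sweeps, and a synthetic multi-sequence cohort generator with
    controllable intra- and inter-reader delineation variability.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
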