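Package: pettex
Title: Texture Indices for PET Volumes Under Relative and Absolute SUV
    Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes heterogeneity texture indices from 3D positron
    emission tomography (PET) volumes: gray-level co-occurrence,
    run-length and size-zone matrices built after discretizing
    standardized uptake values (SUV) either between the region minimum
    and maximum (relative resampling) or between fixed SUV bounds
    (absolute resampling). Includes spherical, adaptive-threshold and
    relocated volumes of interest, conversion of activity concentration
    to body-weight SUV, NIfTI-1 input/output, simulators for a uniform
    FDG phantom with spatially correlated noise and for a synthetic
    non-small cell lung cancer cohort, and the statistical machinery
    (Spearman volume/SUV profiles, Wilcoxon tissue and subtype
    comparisons) used to characterize how the resampling scheme controls
    the volume dependence and tissue discrimination of the indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
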