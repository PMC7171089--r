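Package: devbrainmap
Title: Developmental Whole-Brain Cell-Density Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative mapping of fluorescently labeled cells in
    postnatally developing mouse brains: construction of age-specific average
    template volumes from registered subjects, propagation of hierarchical
    anatomical labels across ages (including sequential routes through an
    intermediate age), multi-resolution affine plus B-spline volume
    registration, per-region cell counts and densities with ontology
    aggregation, layer-specific cortical flatmap binning, and group
    comparisons of regional counts under a negative binomial model with
    Benjamini-Hochberg false-discovery-rate control. A synthetic phantom-brain
    generator with known ground truth (geometry, deformations, and simulated
    cell point sets) makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    MASS,
    limma,
    stats,
    RNifti,
    tiff,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
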