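Package: cellsociology
Title: Cell Sociology Analysis of Multiplex-Stained Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial cell-cell interactions ("cell sociology") in
    multiplex immunohistochemistry images of tissue. Provides constrained
    alternating-least-squares spectral unmixing of hyperspectral image cubes
    into per-stain concentration maps, iterative Otsu nuclei segmentation
    with watershed splitting, threshold-based cell phenotyping with a binary
    decision tree and overlap conflict resolution, Voronoi-adjacency
    neighbor graphs clipped to a region of interest, per-phenotype neighbor
    frequencies and densities, fixed-position label-permutation Monte Carlo
    z-scores for non-randomness, cohort-level rank-sum comparisons with an
    ROI-level classification-benefit score, and synthetic-tissue generators
    for end-to-end validation without patient material.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    jsonlite,
    pracma,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
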