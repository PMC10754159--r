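Package: morphotox
Title: Single-Cell Morphological Profiling of Particulate Matter Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based profiling of cultured airway epithelial
    cells exposed to particulate matter mixtures. Computes 33 cell and
    nuclear size/shape parameters from paired label masks together with
    mean nuclear gamma-H2AX intensity, log-normalizes and embeds cells
    with UMAP, selects the number of k-means morphology clusters by an
    inertia/silhouette plateau criterion, groups clusters into
    cluster-groups by Ward linkage, summarises populations as
    cluster-fraction profiles with Shannon-entropy heterogeneity, and
    ranks cell populations by a dose-response susceptibility score based
    on the loss of large "healthy" morphologies. Includes a synthetic
    single-cell generator (parametric ellipse shapes with planted subtype
    structure, condition shifts, damage levels, and clone panels) so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    uwot,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
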