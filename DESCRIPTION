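Package: phenorose
Title: Simulated Rosette Phenotyping and Drought-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking top-view shoot phenotyping of Arabidopsis
    rosettes. Generates ground-truthed synthetic rosette scenes (RGB and
    dark-adapted chlorophyll-fluorescence rasters) under control and
    water-withholding regimes, segments shoots from substrate by HSB
    thresholding, extracts the standard shape, color and fluorescence trait
    set (projected area, perimeter, convex hull area and perimeter, area by
    circumference, compactness, stockiness, surface coverage, HSB summaries,
    F0, Fm, Fv/Fm), fits per-plant exponential and quadratic growth models,
    and computes drought-response statistics: chamber correction,
    control-normalized trait ratios, per-day standardized PCA, per-day
    ANOVA with Tukey or Dunnett comparisons against pooled wild type,
    size-matched trait curves, and relative water content.
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
    stats,
    grDevices,
    utils,
    tools,
    png,
    tiff,
    EBImage,
    igraph,
    pracma,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
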