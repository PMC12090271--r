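Package: flytube
Title: Quantification of Two-Choice Tube Olfactory Assays in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying two-way choice ("tube") olfactory
    preference assays in walking insects. Computes the per-frame normalized
    center of mass (CoM) and avoidance index of thresholded video frames,
    downsamples traces and averages them over odor-specific steady-state
    windows, calibrates replicate variance and effect size against the
    number of animals per tube, and quantifies stimulus-evoked traces
    (electroantennogram, fluorescence, whole-cell current) by
    peak-minus-baseline rules with exclusion filters. Includes an
    agent-based simulator (biased random walk with crowding) and a frame
    renderer so every analysis stage can be exercised on fully synthetic
    data, plus nonparametric group-comparison helpers (Mann-Whitney,
    Kruskal-Wallis with Dunn's post hoc, paired Wilcoxon).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
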