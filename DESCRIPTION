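Package: chiralpmf
Title: Umbrella Sampling, WHAM and Approach Geometry for Chiral-Selective
    RNA Aminoacylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Free-energy analysis toolkit for umbrella-sampling studies of
    the non-enzymatic aminoacylation of an RNA minihelix, the model reaction
    behind the L-amino-acid preference of D-ribose RNA. Builds umbrella
    window schedules along a distance-difference reaction coordinate,
    generates biased reaction-coordinate time series by overdamped Langevin
    dynamics on parametric one-dimensional free-energy surfaces with
    landmark-controlled barrier heights, estimates the potential of mean
    force by the weighted histogram analysis method (WHAM) with Monte Carlo
    bootstrap uncertainties, extracts transition-state locations, barrier
    heights and Boltzmann selectivity ratios, and computes the reaction-site
    approach geometry (Buergi-Dunitz and Flippin-Lodge angles, key
    distances, and the amino-group torsion) from labelled coordinate
    frames. All results are tibbles; fitted objects provide tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
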