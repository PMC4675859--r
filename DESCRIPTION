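Package: mwmpca
Title: Trajectory Metrics, Supervised PCA and Censored Mixed Models for
    Morris Water Maze Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for Morris water maze
    experiments with factorial group designs. Computes seven trajectory
    derived behavioral variables (escape latency, path length, swim
    speed, Gallagher proximity index, Whishaw corridor index,
    thigmotaxis, target-quadrant occupancy) from 10 Hz tracking records,
    summarises them as group-by-session medians, fits a supervised
    (discriminant) principal component analysis with individuals
    projected as supplementary points, decomposes between-group variance
    into between- and within-session parts, and tests group separation
    and pairwise learning differences by session-linked permutation.
    Single-variable analyses include a right-censored Gaussian
    random-intercept regression for latency fitted by maximum likelihood
    with Gauss-Hermite quadrature, repeated-measures ANOVA with Tukey
    post-hoc tests, and Benjamini-Hochberg false discovery rate control.
    A synthetic swim-trajectory generator reproduces the statistical
    structure of a two-genotype by four-treatment cohort so that every
    stage is testable without animal data.
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
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
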