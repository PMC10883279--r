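Package: sampleOT
Title: Sample-Level Optimal Transport Analysis of Single-Cell and Pathomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares multi-scale samples (single-cell transcriptomics or
    pathomics cohorts) by representing each sample as a distribution of cells
    over clusters and computing exact Wasserstein (earth mover's) distances
    between samples, with cluster-to-cluster costs derived from cluster
    medians in a low-dimensional embedding. The resulting sample distance
    matrix feeds unsupervised analyses: diffusion-map embedding with a
    trajectory backbone that ranks samples by a disease progression score,
    and graph-based (Leiden) sample clustering with silhouette-guided
    resolution selection. Interpretation tools identify cell clusters, genes,
    or morphometric features that change along the trajectory (stepwise
    robust Huber trend regression with Wald curve-difference tests) or
    between sample groups (Welch tests on proportions, moderated
    differential expression), together with covariate-association checks and
    benchmark metrics (adjusted Rand index, silhouette, area under the
    precision-recall curve, Friedman-Nemenyi rank tests). Includes a
    synthetic-cohort generator with planted trajectories or sample groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    limma,
    mclust,
    rhdf5,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    cluster,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
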