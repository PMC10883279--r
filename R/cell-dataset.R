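#' Multi-sample clustered cell dataset
#'
#' Container for an integrated cell-by-feature matrix with per-cell sample
#' and cluster labels, plus a low-dimensional embedding used to estimate the
#' cluster-to-cluster transport cost. "Cells" may equally be tissue
#' structures from pathomics pipelines described by morphometric features;
#' the container is agnostic.
#'
#' Cluster names and sample ids are sorted lexicographically once at
#' construction, and every matrix produced downstream (counts, proportions,
#' costs, distances) is indexed by that fixed order.
#'
#' @param features numeric matrix or `Matrix::dgCMatrix`, cells x features
#'   (gene expression or morphometrics). Row names, if present, are cell ids.
#' @param sample_of_cell character/factor vector, one sample id per cell.
#' @param cluster_of_cell character/factor vector, one cluster label per cell.
#' @param embedding optional numeric matrix, cells x E, the coordinates used
#'   for the cost matrix (e.g. principal components). When `NULL`, principal
#'   components of the standardized features are computed and the first
#'   `min(30, D - 1)` kept.
#' @param sample_metadata optional data.frame of per-sample covariates; must
#'   contain a `sample` column or have row names matching the sample ids.
#'
#' @return An object of class `cell_dataset`: a list with elements
#'   `features`, `sample_of_cell`, `cluster_of_cell`, `embedding`,
#'   `sample_ids`, `cluster_names`, `sample_metadata`.
#' @export
cell_dataset <- function(features, sample_of_cell, cluster_of_cell,
                         embedding = NULL, sample_metadata = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (length(sample_of_cell) != n)
    stop("sample_of_cell must have one entry per row of features (", n, ")")
  if (length(cluster_of_cell) != n)
    stop("cluster_of_cell must have one entry per row of features (", n, ")")
  if (anyNA(sample_of_cell) || anyNA(cluster_of_cell))
    stop("missing sample or cluster labels are not allowed; drop those cells first")

  sample_ids <- sort(unique(as.character(sample_of_cell)))
  cluster_names <- sort(unique(as.character(cluster_of_cell)))
  if (length(sample_ids) < 2) stop("at least 2 samples are required")
  if (length(cluster_names) < 2) stop("at least 2 clusters are required")

  if (is.null(embedding)) {
    embedding <- .default_embedding(features)
  } else {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n)
      stop("embedding must have the same number of rows as features")
  }

  if (!is.null(sample_metadata)) {
    sample_metadata <- as.data.frame(sample_metadata)
    if ("sample" %in% names(sample_metadata)) {
      rownames(sample_metadata) <- as.character(sample_metadata$sample)
    }
    missing <- setdiff(sample_ids, rownames(sample_metadata))
    if (length(missing) > 0)
      stop("sample_metadata is missing rows for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    sample_metadata <- sample_metadata[sample_ids, , drop = FALSE]
  }

  structure(
    list(
      features = features,
      sample_of_cell = factor(as.character(sample_of_cell), levels = sample_ids),
      cluster_of_cell = factor(as.character(cluster_of_cell), levels = cluster_names),
      embedding = embedding,
      sample_ids = sample_ids,
      cluster_names = cluster_names,
      sample_metadata = sample_metadata
    ),
    class = "cell_dataset"
  )
}

# PCA fallback when no embedding is supplied: standardized features,
# first min(30, D - 1) components. Constant features are dropped.
.default_embedding <- function(features, n_comp = 30L) {
  x <- as.matrix(features)
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) stop("all features are constant; cannot build an embedding")
  x <- scale(x[, keep, drop = FALSE])
  k <- min(n_comp, ncol(x) - 1L)
  if (k < 1L) k <- 1L
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = k)
  pc$x
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset:", nrow(x$features), "cells,",
      ncol(x$features), "features\n")
  cat("  samples:  L =", length(x$sample_ids), "\n")
  cat("  clusters: K =", length(x$cluster_names), "\n")
  cat("  embedding:", ncol(x$embedding), "dims\n")
  if (!is.null(x$sample_metadata))
    cat("  metadata:", paste(names(x$sample_metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample, per-cluster cell counts
#'
#' @param dataset a [cell_dataset()].
#' @return integer matrix, samples x clusters, in the dataset's fixed
#'   sample/cluster order.
#' @export
cluster_counts <- function(dataset) {
  stopifnot(inherits(dataset, "cell_dataset"))
  tab <- table(dataset$sample_of_cell, dataset$cluster_of_cell)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m[dataset$sample_ids, dataset$cluster_names, drop = FALSE]
}
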