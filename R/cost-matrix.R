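#' Median representation of each cluster
#'
#' The transport cost between two clusters is derived from a single robust
#' representative per cluster: the coordinate-wise median of the embedding
#' rows of the cluster's cells. Medians rather than means reduce the
#' influence of outlier cells.
#'
#' @param dataset a [cell_dataset()].
#' @return numeric matrix, K x E, row names = cluster names.
#' @export
cluster_medians <- function(dataset) {
  stopifnot(inherits(dataset, "cell_dataset"))
  emb <- dataset$embedding
  out <- matrix(NA_real_, length(dataset$cluster_names), ncol(emb),
                dimnames = list(dataset$cluster_names, colnames(emb)))
  for (k in dataset$cluster_names) {
    idx <- which(dataset$cluster_of_cell == k)
    if (length(idx) == 0) stop("cluster has no cells: ", k)
    out[k, ] <- apply(emb[idx, , drop = FALSE], 2, stats::median)
  }
  out
}

#' Cluster-to-cluster transport cost matrix
#'
#' Pairwise dissimilarity between cluster medians. The default is the cosine
#' distance, c_ij = 1 - <M_i, M_j> / (||M_i|| ||M_j||), which ranges in
#' \[0, 2\] and emphasises the direction of the cluster centroid in the
#' embedding rather than its magnitude. Euclidean, Manhattan and Chebyshev
#' alternatives are available for sensitivity analyses.
#'
#' @param medians K x E numeric matrix (see [cluster_medians()]).
#' @param metric one of "cosine", "euclidean", "manhattan", "chebyshev".
#' @return An object of class `cluster_cost`: list with `medians`, `costs`
#'   (symmetric K x K, zero diagonal), `metric_name`.
#' @export
cost_matrix <- function(medians, metric = c("cosine", "euclidean",
                                            "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  medians <- as.matrix(medians)
  if (anyNA(medians)) stop("NaN/NA in medians")
  k <- nrow(medians)

  if (metric == "cosine") {
    nrm <- sqrt(rowSums(medians^2))
    if (any(nrm == 0)) {
      bad <- rownames(medians)[nrm == 0]
      if (is.null(bad)) bad <- which(nrm == 0)
      stop("zero-norm median under cosine metric for cluster(s): ",
           paste(bad, collapse = ", "))
    }
    costs <- 1 - tcrossprod(medians / nrm)
  } else {
    mth <- switch(metric, euclidean = "euclidean",
                  manhattan = "manhattan", chebyshev = "maximum")
    costs <- as.matrix(stats::dist(medians, method = mth))
  }
  costs <- (costs + t(costs)) / 2
  diag(costs) <- 0
  costs[costs < 0] <- 0   # cosine can go -eps from rounding
  dimnames(costs) <- list(rownames(medians), rownames(medians))

  structure(list(medians = medians, costs = costs, metric_name = metric),
            class = "cluster_cost")
}

#' @export
print.cluster_cost <- function(x, ...) {
  cat("cluster_cost:", nrow(x$costs), "clusters, metric =", x$metric_name, "\n")
  invisible(x)
}
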