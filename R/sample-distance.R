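#' Sample-level distance matrix
#'
#' Light wrapper tying a symmetric non-negative L x L matrix to its ordered
#' sample ids. Used for Wasserstein distances and for baseline distances.
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param sample_ids character vector of length L.
#' @return object of class `sample_dist`.
#' @export
sample_dist <- function(values, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must match the matrix dimension")
  if (max(abs(values - t(values))) > 1e-10) stop("matrix is not symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (any(values < 0)) stop("distances must be non-negative")
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids),
            class = "sample_dist")
}

#' @export
print.sample_dist <- function(x, ...) {
  cat("sample_dist:", length(x$sample_ids), "samples, range [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' Pairwise Wasserstein distances between all samples
#'
#' Runs the exact transport solver for every unordered pair of samples,
#' using the MAP cluster proportions as distributions and the cluster cost
#' matrix as ground cost. Only the upper triangle is solved; the lower is
#' mirrored by symmetry.
#'
#' @param proportions a `proportion_model` (see [estimate_proportions()]) or
#'   an L x K matrix of distributions with rows summing to 1.
#' @param costs a `cluster_cost` (see [cost_matrix()]) or a K x K matrix.
#' @return a [sample_dist()] of Wasserstein distances.
#' @export
pairwise_distances <- function(proportions, costs) {
  p <- if (inherits(proportions, "proportion_model")) proportions$proportions
       else as.matrix(proportions)
  cm <- if (inherits(costs, "cluster_cost")) costs$costs else as.matrix(costs)
  if (ncol(p) != nrow(cm))
    stop("number of clusters differs between proportions (", ncol(p),
         ") and costs (", nrow(cm), ")")
  l <- nrow(p)
  w <- matrix(0, l, l)
  for (i in seq_len(l - 1L)) {
    for (j in seq(i + 1L, l)) {
      w[i, j] <- solve_transport(p[i, ], p[j, ], cm)$distance
      w[j, i] <- w[i, j]
    }
  }
  ids <- rownames(p)
  if (is.null(ids)) ids <- paste0("S", seq_len(l))
  sample_dist(w, ids)
}

#' Baseline: cosine distance between raw proportion vectors
#'
#' Benchmark baseline that ignores cluster-to-cluster similarity: the cosine
#' distance between the per-sample cluster proportion vectors.
#'
#' @inheritParams pairwise_distances
#' @return a [sample_dist()].
#' @export
proportion_baseline_distance <- function(proportions) {
  p <- if (inherits(proportions, "proportion_model")) proportions$proportions
       else as.matrix(proportions)
  nrm <- sqrt(rowSums(p^2))
  if (any(nrm == 0)) stop("zero proportion vector")
  d <- 1 - tcrossprod(p / nrm)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0
  ids <- rownames(p)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(p)))
  sample_dist(d, ids)
}

#' End-to-end Wasserstein distance computation from a dataset
#'
#' Convenience pipeline: MAP proportions, cluster medians, cost matrix, and
#' pairwise exact transport distances.
#'
#' @param dataset a [cell_dataset()].
#' @param prior_strength Dirichlet prior weight c (see
#'   [estimate_proportions()]).
#' @param metric cost metric (see [cost_matrix()]).
#' @return list with `distances` ([sample_dist()]), `proportions`
#'   (`proportion_model`), `costs` (`cluster_cost`).
#' @export
wasserstein_distances <- function(dataset, prior_strength = 0.1,
                                  metric = "cosine") {
  props <- estimate_proportions(dataset, prior_strength)
  costs <- cost_matrix(cluster_medians(dataset), metric)
  list(distances = pairwise_distances(props, costs),
       proportions = props, costs = costs)
}
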