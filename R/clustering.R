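#' Graph-based clustering of samples from a distance matrix
#'
#' Builds a k-nearest-neighbour graph from the sample distance matrix (an
#' edge between i and j when either is among the other's k nearest
#' neighbours, weighted 1 / (1 + d)) and partitions it with the Leiden
#' algorithm under the modularity objective. The community-detection seed is
#' fixed, so results are reproducible.
#'
#' @param distances a [sample_dist()] or symmetric matrix.
#' @param resolution Leiden resolution parameter.
#' @param knn neighbours per sample; default `max(5, floor(sqrt(L)))`;
#'   must be < L.
#' @param seed RNG seed for the Leiden refinement (default 0).
#' @return object of class `sample_clustering`: list with `labels` (integer
#'   1..G, named by sample), `resolution`, `silhouette` (under the input
#'   distances; `NA` for a single cluster), `knn`, `seed`.
#' @export
cluster_samples <- function(distances, resolution = 1, knn = NULL, seed = 0L) {
  d <- if (inherits(distances, "sample_dist")) distances$values
       else as.matrix(distances)
  l <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(l))
  if (is.null(knn)) knn <- max(5L, floor(sqrt(l)))
  if (knn >= l) stop("knn must be smaller than the number of samples")

  adj <- matrix(0, l, l)
  for (i in seq_len(l)) {
    nb <- order(d[i, ], ids)[-1][seq_len(knn)]  # skip self, tie-break by id
    adj[i, nb] <- 1 / (1 + d[i, nb])
  }
  adj <- pmax(adj, t(adj))  # union kNN, symmetric weights
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old_seed <- .save_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 weights = igraph::E(g)$weight,
                                 resolution = resolution, n_iterations = 5L)
  labels <- as.integer(igraph::membership(comm))
  names(labels) <- ids

  sil <- if (length(unique(labels)) > 1)
    silhouette_by_labels(d, labels) else NA_real_
  structure(list(labels = labels, resolution = resolution,
                 silhouette = sil, knn = knn, seed = seed),
            class = "sample_clustering")
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample_clustering:", length(x$labels), "samples,",
      length(unique(x$labels)), "clusters, resolution =", x$resolution,
      ", silhouette =", format(x$silhouette), "\n")
  invisible(x)
}

#' Select the Leiden resolution by silhouette
#'
#' Runs [cluster_samples()] over a grid of resolutions and returns the
#' clustering with the highest silhouette under the input distance matrix.
#' Ties are resolved towards the smallest resolution. Grid points that yield
#' a single cluster have no silhouette and cannot be selected.
#'
#' @inheritParams cluster_samples
#' @param grid numeric vector of candidate resolutions.
#' @return the selected `sample_clustering`, with the full grid summary in
#'   attribute `"grid"` (a data.frame of resolution, n_clusters, silhouette).
#' @export
select_resolution <- function(distances, grid = seq(0.1, 1, by = 0.1),
                              knn = NULL, seed = 0L) {
  if (length(grid) == 0) stop("resolution grid is empty")
  grid <- sort(grid)
  runs <- lapply(grid, function(r) cluster_samples(distances, r, knn, seed))
  sils <- vapply(runs, function(x) x$silhouette, numeric(1))
  summary <- data.frame(
    resolution = grid,
    n_clusters = vapply(runs, function(x) length(unique(x$labels)), integer(1)),
    silhouette = sils
  )
  if (all(is.na(sils)))
    stop("every resolution in the grid yields a single cluster; ",
         "widen the grid towards larger resolutions")
  best <- which.max(replace(sils, is.na(sils), -Inf))  # which.max: first max
  out <- runs[[best]]
  attr(out, "grid") <- summary
  out
}
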