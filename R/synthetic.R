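#' Configuration for the synthetic multi-sample generator
#'
#' Defines a cohort of L samples whose cells fall into K clusters, with
#' cluster proportions either drifting along a planted disease time
#' (`scenario = "trajectory"`) or separated between planted sample groups
#' (`scenario = "groups"`). Defaults describe a mid-sized single-cell
#' cohort: 60 samples, 5 clusters, 2,000 cells per sample, a 10-dimensional
#' embedding and 30 genes.
#'
#' @param n_samples number of samples L.
#' @param n_clusters number of cell clusters K.
#' @param cells_per_sample length-2 range (min, max) of cells per sample;
#'   a single number is used for every sample.
#' @param embed_dim embedding dimensionality E.
#' @param n_genes number of gene/feature columns D.
#' @param scenario `"trajectory"` (proportions follow per-cluster constant /
#'   linear / quadratic curves in planted time) or `"groups"` (each planted
#'   group has its own composition with distinct dominant clusters).
#' @param n_groups number of planted groups (groups scenario).
#' @param effect amplitude of the proportion curves / group composition
#'   contrast (larger = stronger compositional signal).
#' @param trend_genes data.frame(gene, cluster, family, effect) of planted
#'   cluster-specific gene trends in planted time; `NULL` plants two genes
#'   per trend family (linear, quadratic, linear_quadratic) in cluster 1
#'   with effect 2.
#' @param noise_sd standard deviation of cell-level Gaussian noise (both
#'   embedding coordinates and gene expression).
#' @param dropout_rate probability that an expression value is zeroed,
#'   mimicking dropout.
#' @param min_separation minimum pairwise Euclidean distance between
#'   cluster centroids in the embedding.
#' @param seed RNG seed; the seed fully determines the generated dataset.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 60L, n_clusters = 5L,
                         cells_per_sample = c(2000L, 2000L),
                         embed_dim = 10L, n_genes = 30L,
                         scenario = c("trajectory", "groups"),
                         n_groups = 3L, effect = 2,
                         trend_genes = NULL,
                         noise_sd = 1, dropout_rate = 0.2,
                         min_separation = 4, seed = 0L) {
  scenario <- match.arg(scenario)
  if (length(cells_per_sample) == 1) cells_per_sample <- rep(cells_per_sample, 2)
  stopifnot(n_samples >= 2, n_clusters >= 2, embed_dim >= 2, n_genes >= 1,
            cells_per_sample[1] >= 1, cells_per_sample[2] >= cells_per_sample[1],
            dropout_rate >= 0, dropout_rate <= 1, noise_sd >= 0)
  if (scenario == "groups" && n_groups > n_clusters)
    stop("need at least one dominant cluster per group (n_groups <= n_clusters)")
  if (is.null(trend_genes)) {
    fams <- rep(c("linear", "quadratic", "linear_quadratic"), each = 2)
    ng <- min(length(fams), n_genes)
    trend_genes <- data.frame(
      gene = paste0("gene", seq_len(ng)),
      cluster = "cluster1",
      family = fams[seq_len(ng)],
      effect = 2
    )
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 cells_per_sample = as.integer(cells_per_sample),
                 embed_dim = as.integer(embed_dim),
                 n_genes = as.integer(n_genes),
                 scenario = scenario, n_groups = as.integer(n_groups),
                 effect = effect, trend_genes = trend_genes,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "synth_config")
}

# Per-cluster proportion curve weights over planted time in [0, 1].
# Families cycle constant / linear up / linear down / quadratic up /
# quadratic down; weights stay positive and are renormalized at every time.
.proportion_weights <- function(t, k_clusters, effect) {
  fams <- rep(c("constant", "linear_up", "linear_down",
                "quadratic_up", "quadratic_down"),
              length.out = k_clusters)
  w <- vapply(seq_len(k_clusters), function(k) {
    switch(fams[k],
           constant = rep(1.5, length(t)),
           linear_up = 0.5 + effect * t,
           linear_down = 0.5 + effect * (1 - t),
           quadratic_up = 0.5 + effect * t^2,
           quadratic_down = 0.5 + effect * (1 - t^2))
  }, numeric(length(t)))
  w / rowSums(w)
}

.group_compositions <- function(n_groups, k_clusters, effect) {
  assign <- rep(seq_len(n_groups), length.out = k_clusters)
  comp <- matrix(0.5, n_groups, k_clusters)
  for (g in seq_len(n_groups)) comp[g, assign == g] <- 0.5 + 5 * effect
  comp / rowSums(comp)
}

.trend_value <- function(family, t, effect) {
  switch(family,
         linear = effect * t,
         quadratic = effect * t^2,
         linear_quadratic = effect * t - effect * t^2,
         stop("unknown trend family in trend_genes: ", family))
}

#' Generate a synthetic multi-sample clustered dataset
#'
#' Draws cluster centroids in the embedding space (rejection-sampled to the
#' configured minimum separation), assigns each sample a planted time or
#' group, draws per-sample cluster counts multinomially from the planted
#' composition, places cells around their cluster centroid with Gaussian
#' noise, and builds gene expression as cluster baseline + planted
#' cluster-specific trends in planted time + noise, with dropout-style
#' zeroing. The RNG state is saved and restored, so generation does not
#' perturb the caller's random stream.
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (a [cell_dataset()]; sample metadata carries
#'   a `status` column: severity terciles for trajectories, the planted
#'   group for groups, plus a random two-level `batch`) and `truth`
#'   (`time` or `groups` per sample, planted `proportions` L x K, and the
#'   `trend_genes` table).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- .save_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(config$seed)

  L <- config$n_samples; K <- config$n_clusters
  E <- config$embed_dim; D <- config$n_genes
  sample_ids <- sprintf("sample%02d", seq_len(L))
  cluster_names <- paste0("cluster", seq_len(K))

  centroids <- .draw_centroids(K, E, config$min_separation)

  if (config$scenario == "trajectory") {
    t_planted <- stats::runif(L)
    planted_p <- .proportion_weights(t_planted, K, config$effect)
    groups <- NULL
    status <- cut(t_planted, breaks = stats::quantile(t_planted, c(0, 1/3, 2/3, 1)),
                  labels = c("control", "mild", "severe"), include.lowest = TRUE)
  } else {
    groups <- factor(rep(paste0("group", seq_len(config$n_groups)),
                         length.out = L))
    comp <- .group_compositions(config$n_groups, K, config$effect)
    planted_p <- comp[as.integer(groups), , drop = FALSE]
    t_planted <- NULL
    status <- groups
  }
  rownames(planted_p) <- sample_ids
  colnames(planted_p) <- cluster_names

  n_cells <- if (config$cells_per_sample[1] == config$cells_per_sample[2])
    rep(config$cells_per_sample[1], L)
  else
    sample(seq(config$cells_per_sample[1], config$cells_per_sample[2]), L,
           replace = TRUE)

  counts <- t(vapply(seq_len(L), function(l)
    as.numeric(stats::rmultinom(1, n_cells[l], planted_p[l, ])),
    numeric(K)))

  total <- sum(counts)
  cell_sample <- character(total); cell_cluster <- character(total)
  pos <- 1L
  for (l in seq_len(L)) for (k in seq_len(K)) {
    nk <- counts[l, k]
    if (nk == 0) next
    idx <- pos:(pos + nk - 1L)
    cell_sample[idx] <- sample_ids[l]
    cell_cluster[idx] <- cluster_names[k]
    pos <- pos + nk
  }

  kidx <- match(cell_cluster, cluster_names)
  embedding <- centroids[kidx, , drop = FALSE] +
    matrix(stats::rnorm(total * E, 0, config$noise_sd), total, E)
  colnames(embedding) <- paste0("E", seq_len(E))

  baseline <- matrix(stats::rnorm(K * D, 0, 1), K, D)
  features <- baseline[kidx, , drop = FALSE] +
    matrix(stats::rnorm(total * D, 0, config$noise_sd), total, D)
  colnames(features) <- paste0("gene", seq_len(D))

  if (config$scenario == "trajectory" && nrow(config$trend_genes) > 0) {
    t_cell <- t_planted[match(cell_sample, sample_ids)]
    for (r in seq_len(nrow(config$trend_genes))) {
      tg <- config$trend_genes[r, ]
      gi <- match(tg$gene, colnames(features))
      if (is.na(gi)) stop("trend gene not in the gene set: ", tg$gene)
      in_cl <- cell_cluster == tg$cluster
      features[in_cl, gi] <- features[in_cl, gi] +
        .trend_value(tg$family, t_cell[in_cl], tg$effect)
    }
  }

  if (config$dropout_rate > 0) {
    drop <- matrix(stats::runif(total * D) < config$dropout_rate, total, D)
    features[drop] <- 0
  }

  rownames(features) <- rownames(embedding) <-
    sprintf("cell%07d", seq_len(total))

  metadata <- data.frame(
    sample = sample_ids,
    status = as.character(status),
    batch = sample(c("batchA", "batchB"), L, replace = TRUE)
  )

  dataset <- cell_dataset(features, cell_sample, cell_cluster,
                          embedding = embedding, sample_metadata = metadata)
  truth <- list(proportions = planted_p,
                trend_genes = config$trend_genes,
                centroids = centroids)
  if (!is.null(t_planted)) truth$time <- stats::setNames(t_planted, sample_ids)
  if (!is.null(groups)) truth$groups <- stats::setNames(as.character(groups),
                                                        sample_ids)
  list(dataset = dataset, truth = truth)
}

.draw_centroids <- function(K, E, min_sep, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    c0 <- matrix(stats::rnorm(K * E, 0, 4), K, E)
    if (K == 1 || min(stats::dist(c0)) >= min_sep) {
      rownames(c0) <- paste0("cluster", seq_len(K))
      return(c0)
    }
  }
  stop("could not place ", K, " centroids with separation ", min_sep,
       " in ", E, " dimensions")
}
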