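#' Robust (MAP) estimation of per-sample cluster proportions
#'
#' Cell counts per cluster vary strongly between samples, and rare clusters
#' are easily missed in samples with low cell coverage. Proportions are
#' therefore estimated under a Dirichlet-multinomial hierarchical model:
#' the count vector of sample l is multinomial with proportion parameter
#' drawn from a Dirichlet prior whose weights follow the global cluster
#' distribution, alpha_k = (N_k / N) * c. The maximum a posteriori estimate
#' adds these "pseudo cell counts" to the observed counts:
#'
#'   p_hat\[l, k\] = (z\[l, k\] + alpha_k) / (N_l + sum(alpha))
#'
#' so every cluster receives positive mass whenever `prior_strength > 0`.
#'
#' @param dataset a [cell_dataset()], or an integer count matrix
#'   (samples x clusters).
#' @param prior_strength total prior weight c (>= 0); default 0.1. With
#'   `c = 0` the estimates are the empirical proportions, and a sample
#'   missing a cluster yields a zero proportion (a warning is emitted).
#'
#' @return An object of class `proportion_model`: list with `counts`
#'   (L x K), `prior_weights` (alpha, length K), `prior_strength`, and
#'   `proportions` (L x K MAP estimates; rows sum to 1).
#' @export
estimate_proportions <- function(dataset, prior_strength = 0.1) {
  counts <- if (inherits(dataset, "cell_dataset")) cluster_counts(dataset)
            else as.matrix(dataset)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.numeric(prior_strength) || length(prior_strength) != 1 ||
      prior_strength < 0)
    stop("prior_strength must be a single non-negative number")

  n_l <- rowSums(counts)
  if (any(n_l == 0)) {
    bad <- rownames(counts)[n_l == 0]
    if (is.null(bad)) bad <- which(n_l == 0)
    stop("sample(s) with zero cells: ", paste(bad, collapse = ", "))
  }
  n_k <- colSums(counts)
  alpha <- n_k / sum(counts) * prior_strength

  if (prior_strength == 0 && any(counts == 0))
    warning("prior_strength = 0 with empty sample/cluster cells: ",
            "some proportions are exactly zero")

  p <- sweep(counts + rep(alpha, each = nrow(counts)), 1,
             n_l + sum(alpha), "/")
  dimnames(p) <- dimnames(counts)

  structure(
    list(counts = counts, prior_weights = alpha,
         prior_strength = prior_strength, proportions = p),
    class = "proportion_model"
  )
}

#' @export
print.proportion_model <- function(x, ...) {
  cat("proportion_model:", nrow(x$counts), "samples x",
      ncol(x$counts), "clusters, prior c =", x$prior_strength, "\n")
  invisible(x)
}
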