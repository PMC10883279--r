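#' Variable-bandwidth Gaussian affinity from a sample distance matrix
#'
#' Builds the affinity W^s(i, j) = exp(-d(i, j)^2 / (eps * rho_i * rho_j))
#' where rho_i is a per-sample bandwidth. The bandwidth is self-tuning:
#' rho_i = mean distance from sample i to its k nearest neighbours,
#' k = max(5, floor(sqrt(L))) by default. Because rho scales linearly with
#' the distances, the affinity is invariant to a global rescaling of the
#' distance matrix.
#'
#' @param distances a [sample_dist()] or symmetric matrix.
#' @param scale global kernel scale eps (> 0), default 2.
#' @param knn number of neighbours for the bandwidth; default
#'   `max(5, floor(sqrt(L)))`; must be < L.
#' @param bandwidths optional fixed length-L bandwidth vector overriding the
#'   self-tuning rule (mainly for analytical checks).
#' @return object of class `diffusion_map` (affinity stage): list with
#'   `affinity`, `scale`, `bandwidths`, `sample_ids`.
#' @export
affinity_matrix <- function(distances, scale = 2, knn = NULL,
                            bandwidths = NULL) {
  d <- if (inherits(distances, "sample_dist")) distances$values
       else as.matrix(distances)
  ids <- rownames(d)
  l <- nrow(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(l))
  if (is.null(knn)) knn <- max(5L, floor(sqrt(l)))
  if (knn >= l) stop("knn must be smaller than the number of samples")
  if (scale <= 0) stop("scale must be positive")
  if (all(d == 0)) stop("degenerate distance matrix: all distances are zero")

  rho <- if (!is.null(bandwidths)) {
    if (length(bandwidths) != l) stop("bandwidths must have length L")
    as.numeric(bandwidths)
  } else vapply(seq_len(l), function(i) {
    nb <- sort(d[i, -i], partial = knn)[seq_len(knn)]
    mean(nb)
  }, numeric(1))
  if (any(rho == 0)) {
    bad <- ids[rho == 0]
    stop("zero bandwidth (sample identical to its ", knn,
         " nearest neighbours): ", paste(bad, collapse = ", "))
  }
  aff <- exp(-d^2 / (scale * outer(rho, rho)))
  aff <- (aff + t(aff)) / 2
  dimnames(aff) <- list(ids, ids)
  structure(list(affinity = aff, scale = scale, bandwidths = rho,
                 sample_ids = ids),
            class = "diffusion_map")
}

#' Diffusion-map transition matrix and spectral coordinates
#'
#' Completes the diffusion map: optionally removes the sampling-density
#' bias of the kernel (the alpha = 1 anisotropic normalization,
#' W^s / (q_i q_j) with q the kernel row sums -- cohorts sample disease
#' stages very unevenly), row-normalizes into a transition matrix
#' M = D^-1 W^s, decomposes its symmetric conjugate D^-1/2 W^s D^-1/2,
#' drops the trivial constant eigenvector (eigenvalue 1), and returns the
#' next `n_comp` eigenvectors of M, each scaled by its eigenvalue, as
#' diffusion coordinates. Eigenvector signs are fixed deterministically
#' (largest-magnitude entry positive).
#'
#' @param embedding a `diffusion_map` from [affinity_matrix()].
#' @param n_comp number of non-trivial diffusion components (default 2).
#' @param density_norm apply the alpha = 1 density normalization before
#'   row-normalizing (default TRUE).
#' @return the completed `diffusion_map`: adds `transition`, `eigenvalues`
#'   (descending, including the trivial leading 1), `eigenvectors` (of M,
#'   trivial first), and `coordinates` (L x n_comp).
#' @export
transition_and_spectrum <- function(embedding, n_comp = 2L,
                                    density_norm = TRUE) {
  stopifnot(inherits(embedding, "diffusion_map"))
  aff <- embedding$affinity
  l <- nrow(aff)
  if (n_comp > l - 1L) stop("n_comp must be <= L - 1")
  if (density_norm) {
    q <- rowSums(aff)
    aff <- aff / outer(q, q)
    aff <- (aff + t(aff)) / 2
  }
  deg <- rowSums(aff)
  if (any(deg <= .Machine$double.eps * l))
    stop("disconnected affinity graph: numerically zero row sum")

  inv_sqrt <- 1 / sqrt(deg)
  sym <- aff * outer(inv_sqrt, inv_sqrt)
  sym <- (sym + t(sym)) / 2
  es <- eigen(sym, symmetric = TRUE)
  keep <- seq_len(n_comp + 1L)
  lambda <- es$values[keep]
  # eigenvectors of M = D^-1 W^s are D^-1/2 times those of the conjugate
  vec <- es$vectors[, keep, drop = FALSE] * inv_sqrt
  for (c in seq_len(ncol(vec))) {
    piv <- which.max(abs(vec[, c]))
    if (vec[piv, c] < 0) vec[, c] <- -vec[, c]
    vec[, c] <- vec[, c] / sqrt(sum(vec[, c]^2))
  }
  coords <- sweep(vec[, -1L, drop = FALSE], 2, lambda[-1L], "*")
  rownames(coords) <- embedding$sample_ids
  colnames(coords) <- paste0("DC", seq_len(n_comp))

  embedding$transition <- aff / deg
  embedding$eigenvalues <- lambda
  embedding$eigenvectors <- vec
  embedding$coordinates <- coords
  embedding
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("diffusion_map:", length(x$sample_ids), "samples, eps =", x$scale)
  if (!is.null(x$coordinates))
    cat(",", ncol(x$coordinates), "components")
  cat("\n")
  invisible(x)
}

#' Diffusion map of a sample distance matrix
#'
#' One-call wrapper: [affinity_matrix()] followed by
#' [transition_and_spectrum()].
#'
#' @inheritParams affinity_matrix
#' @inheritParams transition_and_spectrum
#' @return completed `diffusion_map`.
#' @export
diffusion_map <- function(distances, scale = 2, knn = NULL, n_comp = 2L,
                          density_norm = TRUE) {
  transition_and_spectrum(affinity_matrix(distances, scale, knn),
                          n_comp, density_norm)
}
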