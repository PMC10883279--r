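# Independent oracles and small fixture builders shared across tests.

# Brute-force LP solution of the transportation problem via boot::simplex
# (independent of the package's transportation simplex). One redundant
# equality constraint is dropped to keep the system full-rank.
lp_transport_oracle <- function(p, q, C) {
  K <- length(p)
  A3 <- matrix(0, 2 * K - 1, K * K)
  for (i in seq_len(K)) A3[i, (seq_len(K) - 1) * K + i] <- 1      # row sums
  for (j in seq_len(K - 1)) A3[K + j, (j - 1) * K + seq_len(K)] <- 1
  b3 <- c(p, q[seq_len(K - 1)])
  res <- boot::simplex(a = as.vector(C), A3 = A3, b3 = b3, maxi = FALSE)
  unname(res$value)
}

random_simplex <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}

# Tiny clustered dataset with known counts, for container-level tests.
tiny_dataset <- function(counts = rbind(s1 = c(3, 2), s2 = c(1, 4)),
                         embed_shift = 0) {
  ns <- rownames(counts); ks <- paste0("c", seq_len(ncol(counts)))
  smp <- character(0); cl <- character(0)
  for (i in seq_along(ns)) for (j in seq_along(ks)) {
    smp <- c(smp, rep(ns[i], counts[i, j]))
    cl <- c(cl, rep(ks[j], counts[i, j]))
  }
  n <- length(smp)
  set.seed(99)
  emb <- matrix(rnorm(n * 3), n, 3) +
    3 * (match(cl, ks)) + embed_shift
  feats <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(sprintf("cell%03d", seq_len(n)),
                                  paste0("g", 1:4)))
  cell_dataset(feats, smp, cl, embedding = emb)
}

# ARI by direct pair-counting from the contingency table (independent of
# the package's implementation).
ari_bruteforce <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
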