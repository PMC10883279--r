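test_that("affinity kernel matches analytic values with fixed bandwidths", {
  # 3 samples with pairwise distance sqrt(ln 2), rho = 1, eps = 1:
  # off-diagonal affinity is exactly 0.5
  d0 <- sqrt(log(2))
  d <- matrix(d0, 3, 3); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:3)
  af <- affinity_matrix(d, scale = 1, knn = 2, bandwidths = rep(1, 3))
  expect_equal(unname(diag(af$affinity)), rep(1, 3))
  expect_equal(af$affinity["s1", "s2"], 0.5, tolerance = 1e-12)
})

test_that("self-tuning bandwidth makes the affinity scale invariant", {
  set.seed(41)
  x <- matrix(rnorm(20 * 2), 20)
  d <- as.matrix(dist(x))
  a1 <- affinity_matrix(d, scale = 1)$affinity
  a2 <- affinity_matrix(7.3 * d, scale = 1)$affinity
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("transition matrix is row-stochastic with leading eigenvalue one", {
  set.seed(42)
  d <- as.matrix(dist(matrix(rnorm(15 * 2), 15)))
  dm <- diffusion_map(d)
  expect_equal(unname(rowSums(dm$transition)), rep(1, 15), tolerance = 1e-10)
  expect_equal(dm$eigenvalues[1], 1, tolerance = 1e-8)
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  # trivial eigenvector of the walk operator is constant
  v1 <- dm$eigenvectors[, 1]
  expect_lt(stats::sd(v1 / mean(v1)), 1e-6)
})

test_that("spectrum agrees with a dense eigen oracle on the walk operator", {
  set.seed(43)
  d <- as.matrix(dist(matrix(rnorm(12 * 2), 12)))
  dm <- diffusion_map(d, n_comp = 3, density_norm = FALSE)
  M <- dm$transition
  es <- eigen(M)             # non-symmetric dense solver as oracle
  ord <- order(-Re(es$values))
  expect_equal(dm$eigenvalues, Re(es$values[ord][1:4]), tolerance = 1e-8)
  for (c in 2:4) {
    v_mine <- dm$eigenvectors[, c]
    v_orac <- Re(es$vectors[, ord[c]])
    cs <- abs(sum(v_mine * v_orac) /
                sqrt(sum(v_mine^2) * sum(v_orac^2)))
    expect_equal(cs, 1, tolerance = 1e-8)
  }
})

test_that("first diffusion coordinate recovers a 1-D chain ordering", {
  L <- 25
  d <- abs(outer(seq_len(L), seq_len(L), "-"))
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(L))
  dm <- diffusion_map(d)
  r <- cor(dm$coordinates[, 1], seq_len(L), method = "spearman")
  expect_gte(abs(r), 0.999)
})

test_that("degenerate affinity inputs error", {
  d <- matrix(0, 5, 5)
  expect_error(affinity_matrix(d, knn = 2), "degenerate|zero")
  d2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_error(affinity_matrix(d2, knn = 5), "knn")
  expect_error(affinity_matrix(d2, scale = -1, knn = 2), "positive")
  expect_error(transition_and_spectrum(affinity_matrix(d2, knn = 2), 5),
               "n_comp")
})
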