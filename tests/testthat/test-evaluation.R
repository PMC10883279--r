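test_that("ARI matches worked examples and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(101)
  for (rep in 1:30) {
    a <- sample(1:4, 25, replace = TRUE)
    b <- sample(1:3, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, a), 1)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("silhouette matches cluster::silhouette and the block example", {
  # two perfect blocks: within 0, between 1
  d <- matrix(1, 6, 6); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  expect_equal(silhouette_by_labels(d, rep(1:2, each = 3)), 1)

  set.seed(102)
  x <- matrix(rnorm(40), 20, 2)
  dd <- as.matrix(dist(x))
  lab <- rep(1:4, each = 5)
  ref <- mean(cluster::silhouette(lab, dmatrix = dd)[, "sil_width"])
  expect_equal(silhouette_by_labels(dd, lab), ref, tolerance = 1e-12)
  expect_error(silhouette_by_labels(dd, rep(1, 20)), "two clusters")
})

test_that("random labels on uniform distances give silhouette near zero", {
  set.seed(103)
  L <- 30
  d <- matrix(1, L, L) + matrix(runif(L * L, 0, 1e-3), L, L)
  d <- (d + t(d)) / 2; diag(d) <- 0
  s <- mean(replicate(40, silhouette_by_labels(d, sample(1:2, L, TRUE))))
  expect_lt(abs(s), 0.05)
})

test_that("AUCPR handles perfect, reversed, and chance orderings", {
  score <- 1:10
  lab <- rep(c(0, 1), each = 5)       # positives ranked last
  a <- aucpr_ordering(score, lab)
  expect_equal(as.numeric(a), 1)
  # reversing the score does not change the result (max of orientations)
  expect_equal(as.numeric(aucpr_ordering(-score, lab)), 1)
  # chance-level: permuted scores average near prevalence
  set.seed(104)
  lab2 <- rep(c(0, 1), c(30, 10))
  ap <- replicate(300, as.numeric(aucpr_ordering(sample(40), lab2)))
  # orientation-max inflates the null slightly above prevalence
  expect_gt(mean(ap), 0.25)
  expect_lt(mean(ap), 0.45)
  expect_error(aucpr_ordering(1:5, rep(1, 5)), "two classes")
})

test_that("Spearman vs ordinal severity matches the rank formula", {
  expect_equal(spearman_vs_ordinal(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_equal(spearman_vs_ordinal(1:5, 1:5)$rho, 1)
  expect_equal(spearman_vs_ordinal(1:5, 5:1)$rho, -1)
  expect_equal(spearman_vs_ordinal(1:5, 5:1)$abs_rho, 1)
  expect_error(spearman_vs_ordinal(1:5, rep(2, 5)), "constant")
})

test_that("Friedman statistic matches stats::friedman.test", {
  set.seed(105)
  scores <- matrix(runif(4 * 12), 4, 12,
                   dimnames = list(paste0("m", 1:4), paste0("d", 1:12)))
  bt <- friedman_nemenyi(scores)
  ref <- stats::friedman.test(t(scores))   # datasets as blocks
  # friedman.test ranks small=1; ours ranks large=1 -- the statistic is
  # invariant to reversing all ranks
  expect_equal(bt$friedman_statistic, unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(bt$friedman_p, ref$p.value, tolerance = 1e-10)
  expect_true(all(abs(bt$pairwise_p - t(bt$pairwise_p)) < 1e-15))
})

test_that("Nemenyi p-values match the two-method closed form", {
  # with k = 2 the studentized range reduces to a two-sided normal test
  set.seed(106)
  scores <- matrix(runif(2 * 10), 2, 10)
  bt <- friedman_nemenyi(scores)
  diff <- abs(bt$mean_ranks[1] - bt$mean_ranks[2])
  z <- unname(diff) / sqrt(2 * 3 / (6 * 10))
  expect_equal(bt$pairwise_p[1, 2], 2 * (1 - pnorm(z)), tolerance = 1e-6)
})

test_that("rank degeneracies behave as documented", {
  scores <- matrix(5, 3, 4)            # all methods identical
  bt <- friedman_nemenyi(scores)
  expect_equal(bt$friedman_p, 1)
  expect_true(all(bt$ranks == 2))      # average rank everywhere
  # a strictly dominant method gets mean rank 1
  s2 <- rbind(best = c(3, 4, 5), worse = c(1, 2, 3), worst = c(0, 1, 2))
  bt2 <- friedman_nemenyi(s2)
  expect_equal(unname(bt2$mean_ranks["best"]), 1)
  expect_error(friedman_nemenyi(matrix(c(1, NA, 2, 3, 4, 5), 2)), "NA")
})
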