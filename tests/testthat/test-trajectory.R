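test_that("collinear samples are ranked left to right from the root", {
  L <- 8
  coords <- cbind(seq_len(L), rep(0, L))
  rownames(coords) <- sprintf("s%02d", seq_len(L))
  tr <- fit_backbone_and_progression(coords, root = "s01")
  expect_identical(unname(tr$progression), 1:8)
  expect_identical(tr$progression[["s01"]], 1L)

  # reversing the root reverses the ranking exactly
  tr_rev <- fit_backbone_and_progression(coords, root = "s08")
  expect_identical(unname(tr_rev$progression), 8:1)
  expect_identical(unname(tr$progression + tr_rev$progression),
                   rep(9L, L))
})

test_that("progression recovers a noisy C-shaped arc", {
  set.seed(51)
  L <- 40
  t_arc <- sort(runif(L, 0, pi))
  coords <- cbind(cos(t_arc), sin(t_arc)) +
    matrix(rnorm(2 * L, 0, 0.03), L)
  rownames(coords) <- sprintf("s%02d", seq_len(L))
  tr <- fit_backbone_and_progression(coords,
                                     root = rownames(coords)[1])
  r <- cor(tr$progression, seq_len(L), method = "spearman")
  expect_gte(abs(r), 0.95)
})

test_that("progression is invariant to sample order permutation", {
  set.seed(52)
  L <- 20
  coords <- cbind(seq_len(L) + rnorm(L, 0, 0.1), rnorm(L, 0, 0.3))
  rownames(coords) <- sprintf("s%02d", seq_len(L))
  tr <- fit_backbone_and_progression(coords, root = "s01")
  perm <- sample(L)
  tr_p <- fit_backbone_and_progression(coords[perm, ], root = "s01")
  expect_identical(tr$progression[rownames(coords)],
                   tr_p$progression[rownames(coords)])
})

test_that("trajectory errors are informative", {
  coords <- cbind(1:10, 0)
  rownames(coords) <- paste0("s", 1:10)
  expect_error(fit_backbone_and_progression(coords, root = "nope"),
               "not found")
  expect_error(fit_backbone_and_progression(coords[1:3, ]), "at least 4")
})

test_that("combined progressions sum and re-rank deterministically", {
  a <- c(s1 = 1, s2 = 2, s3 = 3)
  b <- c(s1 = 3, s2 = 2, s3 = 1)
  # all sums tie: tie broken by sample id order
  expect_identical(combine_progressions(list(a, b)),
                   c(s1 = 1L, s2 = 2L, s3 = 3L))
  # identical inputs reproduce the input ranking
  cc <- c(s1 = 1, s2 = 3, s3 = 2)
  expect_identical(combine_progressions(list(cc, cc)),
                   c(s1 = 1L, s2 = 3L, s3 = 2L))
  expect_error(combine_progressions(list(a, c(s1 = 1, sX = 2, s3 = 3))),
               "different samples")
})
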