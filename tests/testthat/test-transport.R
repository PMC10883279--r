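test_that("transport worked examples solve exactly", {
  # identical distributions: zero distance, diagonal plan
  p <- c(0.3, 0.7)
  r <- solve_transport(p, p, matrix(c(0, 1, 1, 0), 2))
  expect_equal(r$distance, 0)
  expect_equal(unname(r$plan), diag(p), tolerance = 1e-12)

  r2 <- solve_transport(c(1, 0), c(0, 1), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(r2$distance, 0.5)
  expect_equal(r2$plan[1, 2], 1)

  r3 <- solve_transport(c(0.5, 0.5), c(1, 0), matrix(c(0, 1, 1, 0), 2))
  expect_equal(r3$distance, 0.5)
})

test_that("plans satisfy marginal and mass constraints on random instances", {
  set.seed(21)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    p <- random_simplex(K); q <- random_simplex(K)
    C <- matrix(runif(K * K), K, K); diag(C) <- 0
    r <- solve_transport(p, q, C)
    expect_true(all(r$plan >= -1e-12))
    expect_equal(unname(rowSums(r$plan)), p, tolerance = 1e-8)
    expect_equal(unname(colSums(r$plan)), q, tolerance = 1e-8)
    expect_equal(sum(r$plan), 1, tolerance = 1e-8)
    expect_equal(r$distance, sum(r$plan * C), tolerance = 1e-10)
  }
})

test_that("solver matches the independent LP oracle", {
  set.seed(22)
  for (rep in 1:60) {
    K <- sample(2:4, 1)
    p <- random_simplex(K); q <- random_simplex(K)
    C <- matrix(runif(K * K), K, K); diag(C) <- 0
    expect_equal(solve_transport(p, q, C)$distance,
                 lp_transport_oracle(p, q, C), tolerance = 1e-8)
  }
})

test_that("sparse and degenerate distributions are handled", {
  # zero-mass clusters on both sides
  p <- c(0.5, 0, 0.5, 0); q <- c(0, 1, 0, 0)
  C <- as.matrix(stats::dist(matrix(1:4, 4)))
  r <- solve_transport(p, q, C)
  expect_equal(unname(rowSums(r$plan)), p, tolerance = 1e-12)
  expect_equal(unname(colSums(r$plan)), q, tolerance = 1e-12)
  expect_equal(r$distance, 0.5 * 1 + 0.5 * 1)   # masses at 1 and 3 move to 2
})

test_that("distance scales linearly with the cost matrix", {
  set.seed(23)
  K <- 4
  p <- random_simplex(K); q <- random_simplex(K)
  C <- matrix(runif(K * K), K, K); diag(C) <- 0
  base <- solve_transport(p, q, C)$distance
  for (a in c(0.5, 2, 7)) {
    expect_equal(solve_transport(p, q, a * C)$distance, a * base,
                 tolerance = 1e-10)
  }
})

test_that("invalid transport inputs error", {
  C <- matrix(c(0, 1, 1, 0), 2)
  expect_error(solve_transport(c(0.6, 0.6), c(0.5, 0.5), C), "sum to 1")
  expect_error(solve_transport(c(1.2, -0.2), c(0.5, 0.5), C), "non-negative")
  expect_error(solve_transport(c(0.5, 0.5), c(0.5, 0.5),
                               matrix(c(0, Inf, 1, 0), 2)), "finite")
})
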