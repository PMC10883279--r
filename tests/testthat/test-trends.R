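test_that("noiseless linear data is fit exactly", {
  p <- seq(0, 1, length.out = 50)
  f <- fit_trend_models(2 * p, p)
  expect_identical(f$family, "linear")
  expect_equal(unname(f$coefficients[1]), 2, tolerance = 1e-8)
  expect_equal(f$r2_mod, 1, tolerance = 1e-8)
  expect_lt(f$p_value, 1e-10)
})

test_that("planted quadratic curvature is identified within 10%", {
  set.seed(71)
  n <- 200
  p <- runif(n)
  y <- p^2 + rnorm(n, 0, 0.05)
  f <- fit_trend_models(y, p)
  expect_true(f$family %in% c("quadratic", "linear_quadratic"))
  b2 <- if (f$family == "quadratic") f$coefficients[["b1"]]
        else f$coefficients[["b2"]]
  expect_equal(unname(b2), 1, tolerance = 0.1)
})

test_that("large delta reduces Huber to ordinary least squares", {
  set.seed(72)
  p <- runif(60); y <- 1 + 3 * p + rnorm(60, 0, 0.3)
  f <- fit_trend_models(y, p, delta = 1e6, rescale = FALSE)
  ols <- stats::lm(y ~ p)
  expect_equal(unname(f$fits$linear$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("Huber coefficients and standard errors match MASS::rlm", {
  set.seed(73)
  p <- runif(100); y <- 2 - p + rnorm(100, 0, 0.4)
  y[1:3] <- y[1:3] + 5
  f <- fit_trend_models(y, p, delta = 1.345, rescale = FALSE)
  m <- MASS::rlm(y ~ p, psi = MASS::psi.huber, k = 1.345, maxit = 200)
  expect_equal(unname(f$fits$linear$coefficients),
               unname(coef(m)), tolerance = 1e-4)
  se_mine <- sqrt(diag(f$fits$linear$cov))
  expect_equal(unname(se_mine), unname(sqrt(diag(vcov(m)))),
               tolerance = 5e-3)
})

test_that("a gross outlier barely moves the Huber slope but moves OLS", {
  set.seed(74)
  n <- 200
  p <- runif(n); y <- 2 * p + rnorm(n, 0, 0.2)
  b_clean <- fit_trend_models(y, p)$coefficients[[1]]
  y_out <- y; y_out[1] <- y_out[1] + 10 * 0.2 * 10
  shift_huber <- abs(fit_trend_models(y_out, p)$coefficients[[1]] - b_clean)
  shift_ols <- abs(fit_trend_models(y_out, p, delta = 1e6)$coefficients[[1]] -
                     b_clean)
  expect_lt(shift_huber / abs(b_clean), 0.25)
  expect_gt(shift_ols, shift_huber)
})

test_that("IRLS is independent of observation order and converges", {
  set.seed(75)
  n <- 80
  p <- runif(n); y <- 1 + p + rnorm(n, 0, 0.5); y[5] <- 40
  f1 <- fit_trend_models(y, p)
  perm <- sample(n)
  f2 <- fit_trend_models(y[perm], p[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_true(all(vapply(f1$fits, function(x) x$converged, logical(1))))
})

test_that("degenerate trend inputs behave as documented", {
  p <- seq(0, 1, length.out = 20)
  f <- fit_trend_models(rep(3, 20), p)        # constant feature
  expect_identical(f$family, "none")
  expect_identical(f$p_value, 1)
  expect_error(fit_trend_models(rnorm(20), rep(0.5, 20)), "constant")
  expect_error(fit_trend_models(rnorm(5), seq_len(5)), "10 observations")
})

test_that("family selection is mostly correct at moderate noise", {
  set.seed(76)
  n <- 200
  for (fam in c("linear", "quadratic", "linear_quadratic")) {
    hits <- replicate(40, {
      p <- runif(n)
      sig <- switch(fam, linear = 2 * p, quadratic = 2 * p^2,
                    linear_quadratic = 3 * p - 3 * p^2)
      y <- sig + rnorm(n, 0, sqrt(var(sig) / 10))
      fit_trend_models(y, p)$family == fam
    })
    expect_gte(mean(hits), 0.8)
  }
})

test_that("trend screening table is tidy and BH-adjusted", {
  set.seed(77)
  n <- 120
  p <- runif(n)
  mat <- cbind(up = 2 * p + rnorm(n, 0, 0.2),
               flat = rnorm(n, 0, 1),
               curve = 2 * p^2 + rnorm(n, 0, 0.2))
  tab <- fit_trends(mat, p)
  expect_setequal(tab$feature, c("up", "flat", "curve"))
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_identical(tab$family[tab$feature == "flat"], "none")
  expect_identical(tab$feature[1] %in% c("up", "curve"), TRUE)
})
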