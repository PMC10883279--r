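test_that("Welch test matches the hand-computed reference", {
  # groups (1,2,3) vs (4,5,6): t = -3/sqrt(2/3), Satterthwaite dof = 4
  P <- matrix(c(1, 2, 3, 4, 5, 6) / 10, 6, 1,
              dimnames = list(paste0("s", 1:6), "cl"))
  g <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  res <- welch_proportion_test(P, g, "cl")
  t_ref <- (mean(1:3) - mean(4:6)) / sqrt(1 / 3 + 1 / 3)
  expect_equal(res$statistic, t_ref, tolerance = 1e-6)
  expect_equal(res$statistic, -3.6742, tolerance = 1e-4)
  expect_equal(res$dof, 4, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * stats::pt(t_ref, 4), tolerance = 1e-9)
  expect_equal(res$p_value, 0.0214, tolerance = 5e-3)

  # swapping groups negates t, keeps p
  res_sw <- welch_proportion_test(P, g, "cl", group_a = "B", group_b = "A")
  expect_equal(res_sw$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
})

test_that("identical constant groups give t = 0, p = 1", {
  P <- matrix(0.5, 6, 1, dimnames = list(paste0("s", 1:6), "cl"))
  g <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  res <- welch_proportion_test(P, g, "cl")
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
})

test_that("all-pairs Welch screening adjusts within one family", {
  set.seed(91)
  P <- matrix(runif(24), 8, 3,
              dimnames = list(paste0("s", 1:8), paste0("c", 1:3)))
  P <- P / rowSums(P)
  g <- setNames(rep(c("A", "B"), 4), paste0("s", 1:8))
  tab <- welch_proportion_tests(P, g)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$p_adjusted >= tab$p_value))
})

test_that("BH adjustment reproduces the worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # monotone and >= raw for random vectors
  set.seed(92)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("moderated DE ranks a spiked gene first and excludes constants", {
  set.seed(93)
  sim <- generate_dataset(synth_config(n_samples = 8, cells_per_sample = 150,
                                       n_genes = 40, scenario = "groups",
                                       n_groups = 2, dropout_rate = 0,
                                       seed = 7))
  ds <- sim$dataset
  g <- sim$truth$groups
  # spike gene20 in cluster1 cells of group2 samples
  idx <- ds$cluster_of_cell == "cluster1" &
    g[as.character(ds$sample_of_cell)] == "group2"
  ds$features[idx, "gene20"] <- ds$features[idx, "gene20"] + 3
  ds$features[, "gene1"] <- 0   # constant gene
  tab <- moderated_de_test(ds, "cluster1", g)
  expect_identical(tab$feature[1], "gene20")
  expect_lt(tab$p_adjusted[1], 1e-6)
  expect_true("gene1" %in% attr(tab, "excluded"))
  expect_false("gene1" %in% tab$feature)
})

test_that("moderated DE null p-values are roughly uniform", {
  set.seed(94)
  n_cells <- 120
  expr <- matrix(rnorm(n_cells * 300), n_cells, 300,
                 dimnames = list(NULL, paste0("g", 1:300)))
  smp <- rep(paste0("s", 1:8), each = 15)
  ds <- cell_dataset(expr, smp, rep(c("k1", "k2"), n_cells / 2),
                     embedding = matrix(rnorm(n_cells * 2), n_cells))
  g <- setNames(rep(c("A", "B"), 4), paste0("s", 1:8))
  tab <- moderated_de_test(ds, "k1", g)
  expect_gt(mean(tab$p_value), 0.4)
  expect_lt(mean(tab$p_value), 0.6)
  expect_lt(mean(tab$p_value < 0.05), 0.12)
})

test_that("association tests use the right test per covariate type", {
  set.seed(95)
  L <- 40
  labels <- setNames(rep(1:2, each = L / 2), sprintf("s%02d", 1:L))
  cl <- structure(list(labels = labels, resolution = 1, silhouette = 0.5,
                       knn = 5, seed = 0), class = "sample_clustering")
  meta <- data.frame(
    sample = names(labels),
    status = ifelse(labels == 1, "ctrl", "case"),   # identical to clustering
    noise = rnorm(L),
    single = "only_level"
  )
  expect_message(tab <- association_tests(cl, meta), "single")
  expect_setequal(tab$covariate, c("status", "noise"))
  expect_identical(tab$test[tab$covariate == "status"], "chi_squared")
  expect_lt(tab$p_value[tab$covariate == "status"], 1e-6)
  expect_identical(tab$test[tab$covariate == "noise"], "anova")

  prog <- setNames(seq_len(L), names(labels))
  tr <- structure(list(progression = prog), class = "trajectory_result")
  meta2 <- data.frame(sample = names(labels),
                      sev = rep(c("a", "b"), L / 2),
                      score = as.numeric(prog))
  tab2 <- association_tests(tr, meta2)
  expect_identical(tab2$test[tab2$covariate == "sev"], "anova")
  expect_identical(tab2$test[tab2$covariate == "score"], "spearman")
  expect_equal(tab2$statistic[tab2$covariate == "score"], 1)
  expect_lt(tab2$p_value[tab2$covariate == "score"], 1e-10)
})
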