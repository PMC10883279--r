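#' Welch test on cluster proportions between two sample groups
#'
#' Two-sided unequal-variance (Welch) t-test of one cluster's per-sample
#' proportion between two groups of samples, with Satterthwaite degrees of
#' freedom.
#'
#' @param proportions a `proportion_model` ([estimate_proportions()]) or an
#'   L x K proportion matrix; may also be any per-sample numeric matrix.
#' @param groups per-sample group labels (named by sample id, or in row
#'   order), with exactly two levels unless `group_a`/`group_b` name the
#'   pair to compare.
#' @param cluster the cluster (column) to test.
#' @param group_a,group_b optional explicit pair of group labels.
#' @return one-row data.frame: cluster, group_a, group_b, effect (mean
#'   difference a - b), statistic (t), dof, p_value.
#' @export
welch_proportion_test <- function(proportions, groups, cluster,
                                  group_a = NULL, group_b = NULL) {
  p <- if (inherits(proportions, "proportion_model")) proportions$proportions
       else as.matrix(proportions)
  if (!cluster %in% colnames(p) && !(is.numeric(cluster) && cluster <= ncol(p)))
    stop("cluster not found: ", cluster)
  groups <- .align_labels(groups, rownames(p), nrow(p))
  lv <- levels(factor(groups))
  if (is.null(group_a)) {
    if (length(lv) != 2)
      stop("groups has ", length(lv), " levels; give group_a and group_b")
    group_a <- lv[1]; group_b <- lv[2]
  }
  xa <- p[groups == group_a, cluster]
  xb <- p[groups == group_b, cluster]
  if (length(xa) < 2 || length(xb) < 2)
    stop("each group needs at least 2 samples")

  res <- tryCatch(stats::t.test(xa, xb, var.equal = FALSE),
                  error = function(cnd) NULL)
  if (is.null(res)) {       # both groups constant
    tt <- 0; dof <- length(xa) + length(xb) - 2; pv <- 1
  } else {
    tt <- unname(res$statistic); dof <- unname(res$parameter)
    pv <- res$p.value
  }
  data.frame(cluster = as.character(cluster), group_a = group_a,
             group_b = group_b, effect = mean(xa) - mean(xb),
             statistic = tt, dof = dof, p_value = pv)
}

#' Welch tests for all clusters and group pairs
#'
#' Runs [welch_proportion_test()] for every cluster and every unordered
#' pair of group levels, BH-adjusting the p-values as one family.
#'
#' @inheritParams welch_proportion_test
#' @return data.frame with one row per cluster x group pair, including
#'   `p_adjusted`.
#' @export
welch_proportion_tests <- function(proportions, groups) {
  p <- if (inherits(proportions, "proportion_model")) proportions$proportions
       else as.matrix(proportions)
  groups <- .align_labels(groups, rownames(p), nrow(p))
  lv <- levels(factor(groups))
  if (length(lv) < 2) stop("need at least two group levels")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  for (k in colnames(p)) for (pr in pairs)
    rows[[length(rows) + 1L]] <-
      welch_proportion_test(p, groups, k, pr[1], pr[2])
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

.align_labels <- function(labels, ids, n) {
  if (!is.null(names(labels)) && !is.null(ids)) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0)
      stop("labels missing for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[ids]
  }
  if (length(labels) != n) stop("labels must have one entry per sample")
  as.character(labels)
}

#' Moderated differential expression within one cell cluster
#'
#' Contrasts gene expression of the cells of one cluster between two sample
#' groups with limma's empirical-Bayes moderated t-test: gene-wise variances
#' are shrunk toward a common prior (prior degrees of freedom and scale
#' estimated from the observed variance distribution), and the moderated t
#' uses residual-plus-prior degrees of freedom. P-values are BH-adjusted.
#' Genes with zero variance across all included cells are excluded and
#' listed in the `"excluded"` attribute.
#'
#' @param dataset a [cell_dataset()].
#' @param cluster cluster whose cells are compared.
#' @param groups per-sample group labels (two levels), named by sample id
#'   or in `dataset$sample_ids` order.
#' @return data.frame, one row per gene: feature, group_a, group_b, effect
#'   (mean difference, group_b - group_a), statistic (moderated t), dof,
#'   p_value, p_adjusted; sorted by p_value.
#' @export
moderated_de_test <- function(dataset, cluster, groups) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (!cluster %in% dataset$cluster_names)
    stop("cluster not found: ", cluster)
  groups <- .align_labels(groups, dataset$sample_ids,
                          length(dataset$sample_ids))
  names(groups) <- dataset$sample_ids
  lv <- levels(factor(groups))
  if (length(lv) != 2) stop("groups must have exactly two levels")

  idx <- which(dataset$cluster_of_cell == cluster)
  cell_sample <- as.character(dataset$sample_of_cell[idx])
  cell_group <- factor(groups[cell_sample], levels = lv)
  for (g in lv) {
    if (length(unique(cell_sample[cell_group == g])) < 2)
      stop("cluster ", cluster, " has cells from fewer than 2 samples in group ", g)
  }

  expr <- t(as.matrix(dataset$features[idx, , drop = FALSE]))
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("feature", seq_len(nrow(expr)))
  v <- apply(expr, 1, stats::var)
  excluded <- rownames(expr)[v == 0]
  keep <- v > 0
  if (!any(keep)) stop("all genes have zero variance in cluster ", cluster)
  expr <- expr[keep, , drop = FALSE]

  design <- stats::model.matrix(~cell_group)
  fit <- limma::eBayes(limma::lmFit(expr, design))
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")

  out <- data.frame(feature = rownames(expr),
                    group_a = lv[1], group_b = lv[2],
                    effect = tab$logFC,
                    statistic = tab$t,
                    dof = fit$df.total,
                    p_value = tab$P.Value,
                    p_adjusted = bh_adjust(tab$P.Value))
  out <- out[order(out$p_value), , drop = FALSE]
  if (length(excluded) > 0)
    message(length(excluded), " zero-variance gene(s) excluded")
  attr(out, "excluded") <- excluded
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; NA/NaN error.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values)) stop("NA/NaN p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Covariate association tests for clusterings and trajectories
#'
#' Screens per-sample covariates for association with an unsupervised
#' result, to flag both biological signal and technical artefacts (batch,
#' site, chemistry). For a sample clustering: discrete covariates are tested
#' with a chi-squared test of independence, numeric covariates with one-way
#' ANOVA of the covariate across clusters. For a trajectory: discrete
#' covariates with one-way ANOVA of the progression score by level, numeric
#' covariates with a Spearman correlation test. P-values are BH-adjusted
#' across the covariates of the call. Covariates with fewer than two
#' observed levels are skipped and listed in the `"skipped"` attribute.
#'
#' @param result a `sample_clustering` or `trajectory_result`.
#' @param metadata data.frame of per-sample covariates, rows named by (or a
#'   `sample` column giving) the sample ids.
#' @return data.frame: covariate, type, test, statistic, dof, p_value,
#'   p_adjusted.
#' @export
association_tests <- function(result, metadata) {
  if (inherits(result, "sample_clustering")) {
    score <- result$labels; mode <- "clustering"
  } else if (inherits(result, "trajectory_result")) {
    score <- result$progression; mode <- "trajectory"
  } else stop("result must be a sample_clustering or trajectory_result")

  metadata <- as.data.frame(metadata)
  if ("sample" %in% names(metadata)) {
    rownames(metadata) <- as.character(metadata$sample)
    metadata$sample <- NULL
  }
  ids <- names(score)
  missing <- setdiff(ids, rownames(metadata))
  if (length(missing) > 0)
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  metadata <- metadata[ids, , drop = FALSE]

  rows <- list(); skipped <- character(0)
  for (cv in names(metadata)) {
    x <- metadata[[cv]]
    discrete <- is.character(x) || is.factor(x) || is.logical(x)
    if (discrete && length(unique(x[!is.na(x)])) < 2) {
      skipped <- c(skipped, cv); next
    }
    if (!discrete && length(unique(x[!is.na(x)])) < 2) {
      skipped <- c(skipped, cv); next
    }
    if (mode == "clustering" && discrete) {
      tst <- suppressWarnings(stats::chisq.test(table(score, x)))
      rows[[cv]] <- data.frame(covariate = cv, type = "discrete",
                               test = "chi_squared",
                               statistic = unname(tst$statistic),
                               dof = unname(tst$parameter),
                               p_value = tst$p.value)
    } else if (mode == "clustering") {
      fit <- stats::aov(x ~ factor(score))
      an <- stats::anova(fit)
      rows[[cv]] <- data.frame(covariate = cv, type = "numeric",
                               test = "anova",
                               statistic = an[1, "F value"],
                               dof = an[1, "Df"],
                               p_value = an[1, "Pr(>F)"])
    } else if (discrete) {
      fit <- stats::aov(score ~ factor(x))
      an <- stats::anova(fit)
      rows[[cv]] <- data.frame(covariate = cv, type = "discrete",
                               test = "anova",
                               statistic = an[1, "F value"],
                               dof = an[1, "Df"],
                               p_value = an[1, "Pr(>F)"])
    } else {
      tst <- suppressWarnings(
        stats::cor.test(score, x, method = "spearman", exact = FALSE))
      rows[[cv]] <- data.frame(covariate = cv, type = "numeric",
                               test = "spearman",
                               statistic = unname(tst$estimate),
                               dof = NA_real_,
                               p_value = tst$p.value)
    }
  }
  if (length(rows) == 0) stop("no testable covariates")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_adjust(out$p_value)
  if (length(skipped) > 0)
    message("skipped covariate(s) with a single level: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}
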