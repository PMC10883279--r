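#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items
#' (permutation model); 1 for identical partitions (up to relabeling),
#' about 0 for random agreement, can be negative.
#'
#' @param labels_a,labels_b partition labels, equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Silhouette score from a distance matrix
#'
#' Mean silhouette width s(i) = (b - a) / max(a, b) over samples, where a is
#' the mean distance to the sample's own cluster (excluding itself) and b
#' the smallest mean distance to another cluster, computed directly from the
#' distance matrix. Singleton clusters contribute s = 0.
#'
#' @param distances a [sample_dist()] or symmetric matrix.
#' @param labels per-sample cluster labels (>= 2 distinct values).
#' @return scalar in \[-1, 1\].
#' @export
silhouette_by_labels <- function(distances, labels) {
  d <- if (inherits(distances, "sample_dist")) distances$values
       else as.matrix(distances)
  labels <- .align_labels(labels, rownames(d), nrow(d))
  lv <- unique(labels)
  if (length(lv) < 2) stop("silhouette needs at least two clusters")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(lv, labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Area under the precision-recall curve of a progression ordering
#'
#' Measures how well a per-sample score orders a binary label (e.g. disease
#' vs. control): the score is treated as a ranking score for the positive
#' class and the area under the precision-recall curve is computed by
#' step-wise interpolation (average precision). Because the direction of an
#' unsupervised trajectory is arbitrary, both orientations of the score are
#' evaluated and the larger area is returned; the chosen orientation is
#' reported in the `"orientation"` attribute.
#'
#' @param progression numeric scores, one per sample.
#' @param labels binary labels (logical, 0/1, or two-level factor).
#' @param positive the label value counted as positive; default the second
#'   factor level (or `TRUE` / `1`).
#' @return scalar AUCPR in \[0, 1\], attribute `orientation` in
#'   `c("ascending", "descending")`.
#' @export
aucpr_ordering <- function(progression, labels, positive = NULL) {
  if (length(progression) != length(labels))
    stop("progression and labels must have equal length")
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2]
  y <- f == positive
  if (!any(y) || all(y)) stop("both classes must be present")

  up <- .average_precision(progression, y)
  down <- .average_precision(-progression, y)
  if (up >= down) {
    out <- up; orient <- "ascending"
  } else {
    out <- down; orient <- "descending"
  }
  attr(out, "orientation") <- orient
  out
}

# Average precision with tied scores collapsed into single thresholds.
.average_precision <- function(score, y) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; s <- score[ord]
  tp <- cumsum(y)
  n_pos <- sum(y)
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[block_end]
  k <- which(block_end)
  prec <- tp / k
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Spearman correlation of a progression score with ordinal severity
#'
#' Spearman rank correlation (midranks for ties) between per-sample
#' progression scores and an ordered severity encoding (e.g. control = 1,
#' mild = 2, severe = 3), with the p-value of the correlation test. The
#' absolute value is reported alongside for orientation-free comparisons.
#'
#' @param progression numeric scores.
#' @param ordinal integer severity codes, non-constant.
#' @return list: `rho`, `abs_rho`, `p_value`.
#' @export
spearman_vs_ordinal <- function(progression, ordinal) {
  if (length(progression) != length(ordinal))
    stop("progression and ordinal must have equal length")
  if (length(progression) < 3) stop("need at least 3 samples")
  if (length(unique(ordinal)) < 2) stop("ordinal labels are constant")
  tst <- suppressWarnings(
    stats::cor.test(progression, ordinal, method = "spearman", exact = FALSE))
  rho <- unname(tst$estimate)
  list(rho = rho, abs_rho = abs(rho), p_value = tst$p.value)
}

#' Friedman test with Nemenyi post-hoc comparisons
#'
#' Compares methods evaluated on the same collection of datasets by their
#' per-dataset ranks: the Friedman chi-squared test (tie-corrected) for any
#' overall difference, followed by pairwise Nemenyi tests based on the
#' studentized-range distribution of mean-rank differences.
#'
#' @param scores methods x datasets numeric matrix of a performance metric.
#' @param larger_is_better if TRUE (default) larger scores get better
#'   (smaller) ranks.
#' @return object of class `benchmark_table`: `methods`, `datasets`,
#'   `scores`, `ranks` (methods x datasets; average ranks for ties; 1 =
#'   best), `mean_ranks`, `friedman_statistic`, `friedman_p`, `pairwise_p`
#'   (symmetric methods x methods Nemenyi p-values).
#' @export
friedman_nemenyi <- function(scores, larger_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("NA/NaN scores are not allowed")
  k <- nrow(scores); n <- ncol(scores)
  if (k < 2) stop("need at least 2 methods")
  if (n < 3) stop("need at least 3 datasets")
  methods <- rownames(scores)
  if (is.null(methods)) methods <- paste0("method", seq_len(k))
  datasets <- colnames(scores)
  if (is.null(datasets)) datasets <- paste0("dataset", seq_len(n))

  ranks <- apply(if (larger_is_better) -scores else scores, 2, rank)
  dimnames(ranks) <- list(methods, datasets)
  mean_ranks <- rowMeans(ranks)

  # tie-corrected Friedman chi-squared
  ties <- apply(ranks, 2, function(r) {
    tab <- table(r); sum(tab^3 - tab)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  stat <- if (denom <= 0) 0 else
    12 * sum((rowSums(ranks) - n * (k + 1) / 2)^2) / denom
  pval <- if (denom <= 0) 1 else
    stats::pchisq(stat, df = k - 1, lower.tail = FALSE)

  se <- sqrt(k * (k + 1) / (6 * n))
  pairwise <- matrix(1, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    q <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
    pairwise[i, j] <- pairwise[j, i] <-
      stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  }

  structure(list(methods = methods, datasets = datasets, scores = scores,
                 ranks = ranks, mean_ranks = mean_ranks,
                 friedman_statistic = stat, friedman_p = pval,
                 pairwise_p = pairwise),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("benchmark_table:", length(x$methods), "methods x",
      length(x$datasets), "datasets\n")
  cat("  Friedman chi^2 =", format(x$friedman_statistic),
      ", p =", format(x$friedman_p), "\n")
  cat("  mean ranks:\n")
  print(round(sort(x$mean_ranks), 3))
  invisible(x)
}
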