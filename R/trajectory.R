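#' Trajectory backbone and disease-progression ranking
#'
#' Fits a path-structured backbone through the 2-D diffusion coordinates
#' and ranks every sample by its position along it. The backbone is the
#' longest (weighted) path through the Euclidean minimum spanning tree of
#' the coordinates -- the tree diameter -- which traces the dominant
#' one-dimensional structure of the embedding. Each sample is orthogonally
#' projected onto its nearest backbone segment; its progression score is the
#' rank of the arc-length position of that projection, oriented so the root
#' sample sits at the start (rank 1). Ties in arc length are broken by
#' sample id order, so the result is fully deterministic.
#'
#' @param embedding a completed `diffusion_map` (needs `coordinates` with at
#'   least 2 columns) or an L x 2 coordinate matrix with row names.
#' @param root a sample id, or `"auto"`. With `"auto"`, if `status` is
#'   given the root is the sample most extreme on the first diffusion
#'   component among the reference level of `status` (its first factor
#'   level, e.g. controls); otherwise the sample with the minimal first
#'   coordinate.
#' @param status optional per-sample discrete labels (named or in sample
#'   order) used only for `root = "auto"`.
#' @return object of class `trajectory_result`: list with `coordinates`
#'   (L x 2), `backbone` (ordered node coordinates of the path),
#'   `root_sample`, `arc_position` (arc length of each projection) and
#'   `progression` (integer ranks 1..L, named by sample).
#' @export
fit_backbone_and_progression <- function(embedding, root = "auto",
                                         status = NULL) {
  coords <- if (inherits(embedding, "diffusion_map")) embedding$coordinates
            else as.matrix(embedding)
  if (is.null(coords)) stop("embedding has no coordinates; run transition_and_spectrum first")
  if (ncol(coords) < 2) stop("at least 2 diffusion components are required")
  coords <- coords[, 1:2, drop = FALSE]
  l <- nrow(coords)
  if (l < 4) stop("backbone requires at least 4 samples")
  ids <- rownames(coords)
  if (is.null(ids)) ids <- paste0("S", seq_len(l))
  rownames(coords) <- ids

  if (identical(root, "auto")) {
    root <- .auto_root(coords, ids, status)
  } else if (!root %in% ids) {
    stop("root sample not found: ", root)
  }

  # backbone = diameter path of the Euclidean MST
  d <- as.matrix(stats::dist(coords))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g)
  diam <- igraph::get_diameter(tree)
  path_idx <- as.integer(diam)
  backbone <- coords[path_idx, , drop = FALSE]

  proj <- .project_onto_polyline(coords, backbone)

  # orient so the root projects nearer the start than the end
  total <- max(proj$arc)
  if (proj$arc[ids == root] > total - proj$arc[ids == root]) {
    backbone <- backbone[rev(seq_len(nrow(backbone))), , drop = FALSE]
    proj <- .project_onto_polyline(coords, backbone)
  }

  ord <- order(proj$arc, ids)
  progression <- integer(l)
  progression[ord] <- seq_len(l)
  names(progression) <- ids

  structure(list(coordinates = coords, backbone = backbone,
                 root_sample = root, arc_position = proj$arc,
                 progression = progression),
            class = "trajectory_result")
}

.auto_root <- function(coords, ids, status) {
  dc1 <- coords[, 1]
  if (!is.null(status)) {
    status <- if (!is.null(names(status))) status[ids] else status
    if (length(status) != length(ids))
      stop("status must have one entry per sample")
    ref <- levels(factor(status))[1]
    cand <- which(status == ref)
    # the control extreme on DC1: whichever control end is farther out
    if (abs(min(dc1[cand]) - stats::median(dc1)) >=
        abs(max(dc1[cand]) - stats::median(dc1)))
      return(ids[cand[which.min(dc1[cand])]])
    return(ids[cand[which.max(dc1[cand])]])
  }
  ids[which.min(dc1)]
}

# Orthogonal projection of points onto a polyline; returns the arc length
# of each projection measured from the first backbone node.
.project_onto_polyline <- function(points, polyline) {
  nseg <- nrow(polyline) - 1L
  seg_len <- sqrt(rowSums((polyline[-1L, , drop = FALSE] -
                           polyline[-nrow(polyline), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))
  arc <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    best <- Inf; best_arc <- 0
    for (s in seq_len(nseg)) {
      a <- polyline[s, ]; b <- polyline[s + 1L, ]
      ab <- b - a
      denom <- sum(ab^2)
      t <- if (denom == 0) 0 else sum((points[p, ] - a) * ab) / denom
      t <- min(1, max(0, t))
      q <- a + t * ab
      dd <- sum((points[p, ] - q)^2)
      if (dd < best) { best <- dd; best_arc <- cum0[s] + t * seg_len[s] }
    }
    arc[p] <- best_arc
  }
  list(arc = arc)
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result:", length(x$progression), "samples, root =",
      x$root_sample, "\n")
  invisible(x)
}

#' Combine progression scores from parallel analyses
#'
#' When the same cohort yields several trajectories (e.g. independent
#' analyses of glomeruli and tubules in pathomics), the per-sample scores
#' are combined by their element-wise sum and re-ranked 1..L. Ties after
#' summing are broken by sample id order.
#'
#' @param progressions list of numeric vectors over identical samples; named
#'   vectors are aligned by name.
#' @return integer vector of combined ranks, named by sample.
#' @export
combine_progressions <- function(progressions) {
  stopifnot(is.list(progressions), length(progressions) >= 1)
  ref <- names(progressions[[1]])
  for (p in progressions) {
    if (length(p) != length(progressions[[1]]))
      stop("progression vectors differ in length")
    if (!is.null(ref) && !setequal(names(p), ref))
      stop("progression vectors cover different samples")
  }
  aligned <- lapply(progressions, function(p) {
    if (!is.null(ref)) p[ref] else p
  })
  total <- Reduce(`+`, aligned)
  ids <- if (!is.null(ref)) ref else paste0("S", seq_along(total))
  ord <- order(total, ids)
  out <- integer(length(total))
  out[ord] <- seq_along(total)
  names(out) <- ids
  out
}
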