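#' Exact optimal transport between two cluster distributions
#'
#' Solves the discrete Monge-Kantorovich problem
#' min_T sum_ij t_ij c_ij subject to t_ij >= 0, row sums of T equal the
#' source distribution and column sums equal the target distribution. The
#' optimum is found exactly with the transportation simplex (northwest-corner
#' start, MODI pivoting) -- a network-simplex-style solver, not an entropic
#' approximation. The Wasserstein distance is the cost of the optimal plan.
#'
#' @param p_source,p_target non-negative numeric vectors of length K summing
#'   to 1 (deviations up to 1e-8 are renormalized; larger deviations error).
#' @param costs K x K matrix of finite transport costs.
#' @return An object of class `transport_result`: list with `plan` (K x K)
#'   and `distance` (scalar).
#' @export
solve_transport <- function(p_source, p_target, costs) {
  costs <- as.matrix(costs)
  p_source <- as.numeric(p_source)
  p_target <- as.numeric(p_target)
  k <- length(p_source)
  if (length(p_target) != k || nrow(costs) != k || ncol(costs) != k)
    stop("p_source, p_target and costs must share the same K")
  if (any(!is.finite(costs))) stop("costs must be finite")
  if (any(p_source < 0) || any(p_target < 0))
    stop("distributions must be non-negative")
  for (nm in c("p_source", "p_target")) {
    s <- sum(get(nm))
    if (abs(s - 1) > 1e-8)
      stop(nm, " does not sum to 1 (sum = ", format(s), ")")
  }
  p_source <- p_source / sum(p_source)
  p_target <- p_target / sum(p_target)

  plan <- .transport_simplex(p_source, p_target, costs)
  dimnames(plan) <- dimnames(costs)
  structure(list(plan = plan, distance = sum(plan * costs)),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("transport_result: K =", nrow(x$plan),
      " distance =", format(x$distance), "\n")
  invisible(x)
}

# Transportation simplex on the balanced problem a -> b with cost matrix C.
# Zero-mass rows/columns are removed up front and restored afterwards.
.transport_simplex <- function(a, b, C, tol = 1e-12, max_iter = 10000L) {
  m0 <- length(a); n0 <- length(b)
  ri <- which(a > 0); ci <- which(b > 0)
  plan0 <- matrix(0, m0, n0)
  a <- a[ri]; b <- b[ci]; C <- C[ri, ci, drop = FALSE]
  m <- length(a); n <- length(b)

  if (m == 1L) { plan0[ri, ci] <- b; return(plan0) }
  if (n == 1L) { plan0[ri, ci] <- a; return(plan0) }

  # northwest-corner initial basic feasible solution; keeps degenerate
  # zero-allocation cells so the basis is always a spanning tree
  X <- matrix(0, m, n)
  B <- matrix(FALSE, m, n)
  ar <- a; br <- b
  i <- 1L; j <- 1L
  repeat {
    x <- min(ar[i], br[j])
    X[i, j] <- x
    B[i, j] <- TRUE
    ar[i] <- ar[i] - x; br[j] <- br[j] - x
    if (i == m && j == n) break
    if (ar[i] <= br[j] && i < m) i <- i + 1L else j <- j + 1L
  }

  degen_streak <- 0L
  for (iter in seq_len(max_iter)) {
    uv <- .tree_potentials(B, C)
    red <- C - outer(uv$u, uv$v, "+")
    red[B] <- 0
    if (degen_streak > 50L) {
      # Bland-style anti-cycling: first improving cell in column-major order
      cand <- which(red < -tol)
      if (length(cand) == 0) break
      ent <- cand[1L]
    } else {
      if (min(red) >= -tol) break
      ent <- which.min(red)
    }
    ei <- ((ent - 1L) %% m) + 1L
    ej <- ((ent - 1L) %/% m) + 1L

    path <- .tree_path(B, ei, m + ej, m)   # node path row ei -> col ej
    # cells along the path alternate -, +, -, ... starting from (ei, first col)
    n_edges <- length(path) - 1L
    cell_i <- integer(n_edges); cell_j <- integer(n_edges)
    for (e in seq_len(n_edges)) {
      v1 <- path[e]; v2 <- path[e + 1L]
      if (v1 <= m) { cell_i[e] <- v1; cell_j[e] <- v2 - m }
      else         { cell_i[e] <- v2; cell_j[e] <- v1 - m }
    }
    minus <- seq(1L, n_edges, by = 2L)
    plus <- if (n_edges >= 2L) seq(2L, n_edges, by = 2L) else integer(0)
    vals <- X[cbind(cell_i[minus], cell_j[minus])]
    theta <- min(vals)
    leave <- minus[which.min(vals)]

    X[cbind(cell_i[minus], cell_j[minus])] <-
      X[cbind(cell_i[minus], cell_j[minus])] - theta
    if (length(plus))
      X[cbind(cell_i[plus], cell_j[plus])] <-
        X[cbind(cell_i[plus], cell_j[plus])] + theta
    X[ei, ej] <- X[ei, ej] + theta
    B[cell_i[leave], cell_j[leave]] <- FALSE
    X[cell_i[leave], cell_j[leave]] <- 0
    B[ei, ej] <- TRUE

    degen_streak <- if (theta <= tol) degen_streak + 1L else 0L
    if (iter == max_iter) stop("transport solver failed to converge")
  }

  X[X < 0] <- 0
  plan0[ri, ci] <- X
  plan0
}

# Dual potentials (u, v) from the basis spanning tree, u[1] = 0.
.tree_potentials <- function(B, C) {
  m <- nrow(B); n <- ncol(B)
  u <- rep(NA_real_, m); v <- rep(NA_real_, n)
  u[1] <- 0
  adj <- .basis_adjacency(B)
  queue <- 1L
  while (length(queue)) {
    node <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[node]]) {
      if (node <= m && is.na(v[nb - m])) {
        v[nb - m] <- C[node, nb - m] - u[node]; queue <- c(queue, nb)
      } else if (node > m && is.na(u[nb])) {
        u[nb] <- C[nb, node - m] - v[node - m]; queue <- c(queue, nb)
      }
    }
  }
  if (anyNA(u) || anyNA(v)) stop("internal error: basis is not connected")
  list(u = u, v = v)
}

.basis_adjacency <- function(B) {
  m <- nrow(B); n <- ncol(B)
  adj <- vector("list", m + n)
  idx <- which(B, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- m + idx[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Unique path between two nodes in the basis spanning tree (BFS).
.tree_path <- function(B, from, to, m) {
  adj <- .basis_adjacency(B)
  parent <- rep(NA_integer_, m + ncol(B))
  parent[from] <- 0L
  queue <- from
  while (length(queue)) {
    node <- queue[1L]; queue <- queue[-1L]
    if (node == to) break
    for (nb in adj[[node]]) {
      if (is.na(parent[nb])) { parent[nb] <- node; queue <- c(queue, nb) }
    }
  }
  if (is.na(parent[to])) stop("internal error: no path in basis tree")
  path <- to
  while (path[1L] != from) path <- c(parent[path[1L]], path)
  path
}
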