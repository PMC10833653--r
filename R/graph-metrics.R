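#' Threshold a functional connectivity matrix
#'
#' Keeps connectivity values strictly above a nonnegative threshold and sets
#' the rest to zero, avoiding negative weights whose graph-theoretical
#' interpretation is ambiguous.  The diagonal is zeroed: self-correlation is
#' not an edge.
#'
#' @param A symmetric FC matrix.
#' @param tau nonnegative threshold (default 0).
#' @return nonnegative weighted adjacency matrix with zero diagonal.
#' @export
threshold_fc <- function(A, tau = 0) {
  stopifnot(tau >= 0)
  B <- A
  B[B <= tau] <- 0
  diag(B) <- 0
  B
}

#' Weighted Newman modularity of a given partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)` with weighted
#' degrees `k` and total weight `2m = sum(A)`.  The single-community
#' partition has Q = 0 by construction.
#'
#' @param A symmetric nonnegative weighted adjacency, zero diagonal.
#' @param membership integer community labels.
#' @return scalar Q.
#' @export
newman_q <- function(A, membership) {
  m2 <- sum(A)
  if (m2 <= 0) stop("modularity undefined: graph has no edges")
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# Gain-based single-node refinement sweeps (Kernighan-Lin style moves):
# repeatedly move single nodes to the community with the best Q gain.
kl_refine <- function(A, membership, max_passes = 20L) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  membership <- as.integer(membership)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      ci <- membership[i]
      comms <- unique(membership)
      # weight from i to each community (excluding i itself)
      w_i <- vapply(comms, function(cm) {
        sum(A[i, membership == cm]) - if (cm == ci) A[i, i] else 0
      }, numeric(1))
      K <- vapply(comms, function(cm) {
        sum(k[membership == cm]) - if (cm == ci) k[i] else 0
      }, numeric(1))
      gain <- (w_i - k[i] * K / m2) / m2
      gain <- gain - gain[comms == ci]
      best <- which.max(gain)
      if (gain[best] > 1e-12) {
        membership[i] <- comms[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # compact labels
  as.integer(factor(membership))
}

# Leading eigenvector bisection of a (sub)graph under the generalized
# modularity matrix; returns +/-1 signs or NULL if indivisible.
spectral_bisect <- function(B_g) {
  eig <- eigen(B_g, symmetric = TRUE)
  if (eig$values[1] <= 1e-10) return(NULL)
  s <- ifelse(eig$vectors[, 1] >= 0, 1, -1)
  if (length(unique(s)) < 2) return(NULL)
  s
}

#' Community structure by Newman's spectral algorithm
#'
#' Recursive leading-eigenvector bisection of the (generalized) modularity
#' matrix, each split accepted only if it increases Q, followed by
#' Kernighan-Lin style single-node refinement sweeps.  Deterministic for a
#' given matrix.
#'
#' @param A symmetric nonnegative weighted adjacency with zero diagonal.
#' @param refine apply the refinement sweeps.
#' @return list with `Q` (modularity of the returned partition, evaluated by
#'   [newman_q()]) and `membership`.
#' @export
modularity_partition <- function(A, refine = TRUE) {
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be nonnegative (see threshold_fc)")
  n <- nrow(A)
  m2 <- sum(A)
  if (m2 <= 0) stop("modularity undefined: graph has no edges")
  k <- rowSums(A)
  B <- A - outer(k, k) / m2

  membership <- rep(1L, n)
  queue <- list(seq_len(n))
  next_label <- 2L
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    B_g <- B[g, g, drop = FALSE]
    diag(B_g) <- diag(B_g) - rowSums(B_g)
    s <- spectral_bisect(B_g)
    if (is.null(s)) next
    dQ <- as.numeric(t(s) %*% B_g %*% s) / (2 * m2)
    if (dQ <= 1e-12) next
    g2 <- g[s < 0]
    membership[g2] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(g[s > 0]), list(g2))
  }
  if (refine) membership <- kl_refine(A, membership)
  membership <- as.integer(factor(membership))
  list(Q = newman_q(A, membership), membership = membership)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the reciprocal shortest-path length,
#' where an edge's length is the reciprocal of its weight and disconnected
#' pairs contribute zero.  A complete unit-weight graph has E = 1.
#'
#' @param A symmetric nonnegative weighted adjacency with zero diagonal.
#' @param use_igraph use Dijkstra shortest paths from igraph (default); if
#'   `FALSE`, fall back to the dense Floyd-Warshall recursion.
#' @return scalar efficiency in [0, 1] for weights bounded by 1.
#' @export
global_efficiency <- function(A, use_igraph = TRUE) {
  n <- nrow(A)
  if (n < 2) return(0)
  if (use_igraph && sum(A > 0) > 0) {
    L <- A
    L[A > 0] <- 1 / A[A > 0]
    g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    D <- igraph::distances(g, weights = igraph::E(g)$weight,
                           algorithm = "dijkstra")
  } else {
    D <- floyd_warshall(A)
  }
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# All-pairs shortest path lengths by Floyd-Warshall on 1/weight edge
# lengths; independent oracle for global_efficiency.
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1 / A[A > 0]
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

#' Brute-force global efficiency (verification oracle)
#'
#' Same definition as [global_efficiency()] but with all-pairs shortest
#' paths computed by a direct Floyd-Warshall recursion; used to verify the
#' Dijkstra-based implementation on small graphs.
#'
#' @inheritParams global_efficiency
#' @return scalar efficiency.
#' @export
global_efficiency_bruteforce <- function(A) {
  global_efficiency(A, use_igraph = FALSE)
}
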