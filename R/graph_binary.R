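# Binary-graph topology at fixed link density: the strongest edges are kept
# so that graphs compared across subjects always have the same edge count, and
# clustering / path length then reflect topology rather than overall
# connectivity strength.

#' Binarize a connectivity matrix at a link density
#'
#' Retains the `round(density * N(N-1)/2)` strongest edges. Ties at the
#' cutoff weight are broken deterministically by ascending node-index pair
#' `(i, j)`.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @param density fraction of edges to retain, in `(0, 1]`.
#' @return symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize_by_density <- function(cm, density) {
  W <- conn_as_matrix(cm)
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  N <- nrow(W)
  pairs <- upper_pairs(N)
  w <- W[pairs]
  m <- round(density * nrow(pairs))
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  keep <- ord[seq_len(m)]
  A <- matrix(0, N, N)
  A[pairs[keep, , drop = FALSE]] <- 1
  A + t(A)
}

#' Binarize at an absolute threshold
#'
#' Utility only: keeps edges whose weight exceeds a fixed threshold. Because
#' the retained edge count then depends on overall connectivity strength,
#' density-based binarization ([binarize_by_density()]) is what the group
#' pipeline uses.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @param threshold absolute weight cutoff.
#' @return symmetric 0/1 adjacency matrix.
#' @export
binarize_by_threshold <- function(cm, threshold) {
  W <- conn_as_matrix(cm)
  A <- (W > threshold) * 1
  diag(A) <- 0
  A
}

check_binary <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop("need a square matrix")
  if (!all(adj %in% c(0, 1))) stop("adjacency must be binary")
  if (max(abs(adj - t(adj))) > 0) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  adj
}

#' Binary clustering coefficient
#'
#' Per-node: the fraction of existing edges among the node's neighbours;
#' nodes with fewer than two neighbours contribute 0. The network value is
#' the mean over all nodes.
#'
#' @param adj symmetric binary adjacency matrix.
#' @return scalar in `[0, 1]`.
#' @export
binary_clustering <- function(adj) {
  A <- check_binary(adj)
  k <- rowSums(A)
  closed3 <- diag(A %*% A %*% A)  # 2 x (triangles through i)
  cci <- ifelse(k >= 2, closed3 / (k * (k - 1)), 0)
  mean(cci)
}

#' Binary characteristic path length (harmonic mean)
#'
#' Shortest paths counted in edges (breadth-first search); the network value
#' is the harmonic mean over all node pairs, with disconnected pairs
#' contributing zero reciprocal distance.
#'
#' @param adj symmetric binary adjacency matrix.
#' @return scalar path length in edge counts (`Inf` if no pair is connected).
#' @export
binary_path_length <- function(adj) {
  A <- check_binary(adj)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  L <- igraph::distances(g, algorithm = "unweighted")
  1 / mean(1 / L[upper.tri(L)])
}

#' Binary metrics over a sweep of link densities
#'
#' The default grid is 0.2 to 0.9 in steps of 0.05 (15 densities).
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @param densities increasing vector of link densities in `(0, 1]`.
#' @return data frame with one row per density: `density`, `n_edges`, `cc`,
#'   `pl`.
#' @export
density_sweep <- function(cm, densities = seq(0.2, 0.9, by = 0.05)) {
  W <- conn_as_matrix(cm)
  stopifnot(all(densities > 0), all(densities <= 1),
            !is.unsorted(densities, strictly = TRUE))
  res <- lapply(densities, function(d) {
    A <- binarize_by_density(W, d)
    data.frame(density = d, n_edges = sum(A) / 2,
               cc = binary_clustering(A), pl = binary_path_length(A))
  })
  do.call(rbind, res)
}
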