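# Weighted-graph topology. Clustering: CC_i = sum_{k!=i, l!=i,k} w_ik w_il
# w_kl / sum w_ik w_il, CC = mean_i CC_i. Path length: distances d_ij = 1/w_ij,
# shortest paths by Dijkstra, and PL is the harmonic mean over ordered node
# pairs, so disconnected pairs (infinite distance) contribute zero reciprocal
# instead of breaking the mean.

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering as the ratio of triple products
#' `w_ik w_il w_kl` to pair products `w_ik w_il` over ordered neighbour pairs,
#' averaged over all nodes. Nodes with all-zero weights contribute 0.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix
#'   (N >= 3).
#' @return scalar; in `[0, 1]` for weights in `[0, 1]`.
#' @examples
#' W <- matrix(0.4, 3, 3); diag(W) <- 0
#' weighted_clustering(W) # complete triangle with equal weights: CC = w = 0.4
#' @export
weighted_clustering <- function(cm) {
  W <- conn_as_matrix(cm, min_nodes = 3L)
  num <- diag(W %*% W %*% W)          # sum over k != l of w_ik w_kl w_li
  s <- rowSums(W)
  den <- s^2 - rowSums(W^2)           # sum over k != l of w_ik w_il
  cci <- ifelse(den > 0, num / den, 0)
  mean(cci)
}

#' Weighted characteristic path length (harmonic mean)
#'
#' Edge distances are inverse weights (`d = 1/w`, absent for `w = 0`);
#' shortest-path lengths `l_ij` come from Dijkstra's algorithm, and
#' `PL = 1 / mean(1 / l_ij)` over all ordered pairs. Disconnected pairs
#' contribute `1/l = 0`; a graph with no finite pair distances returns `Inf`.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix
#'   (N >= 2).
#' @return scalar harmonic-mean path length (same units as inverse weight).
#' @examples
#' W <- matrix(0.5, 4, 4); diag(W) <- 0
#' weighted_path_length(W) # complete graph, all weights w: PL = 1/w = 2
#' @export
weighted_path_length <- function(cm) {
  W <- conn_as_matrix(cm)
  D <- ifelse(W > 0, 1 / W, 0)  # 0 = no edge for igraph adjacency
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  L <- igraph::distances(g, algorithm = "dijkstra")
  linv <- 1 / L[upper.tri(L)]   # 1/Inf = 0 for disconnected pairs
  1 / mean(linv)
}

#' Surrogate-network normalization of weighted graph metrics
#'
#' Builds an ensemble of surrogate random networks by reshuffling the
#' upper-triangle edge weights uniformly at random (preserving symmetry, the
#' zero diagonal, and the weight multiset), and normalizes the observed
#' clustering coefficient and path length by the surrogate-ensemble means.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @param n_surrogates ensemble size (default 100).
#' @param seed optional integer seed for the reshuffling (the caller's RNG
#'   stream is untouched).
#' @return a `weighted_graph_metrics` object: `cc_raw`, `pl_raw`, `cc_norm`,
#'   `pl_norm`, `n_surrogates`.
#' @export
surrogate_normalize <- function(cm, n_surrogates = 100L, seed = NULL) {
  W <- conn_as_matrix(cm, min_nodes = 3L)
  stopifnot(n_surrogates >= 1L)
  cc_raw <- weighted_clustering(W)
  pl_raw <- weighted_path_length(W)
  ut <- upper.tri(W)
  w <- W[ut]
  run <- function() {
    ccs <- numeric(n_surrogates)
    pls <- numeric(n_surrogates)
    for (s in seq_len(n_surrogates)) {
      Ws <- matrix(0, nrow(W), ncol(W))
      Ws[ut] <- sample(w)
      Ws <- Ws + t(Ws)
      ccs[s] <- weighted_clustering(Ws)
      pls[s] <- weighted_path_length(Ws)
    }
    list(cc = mean(ccs), pl = mean(pls))
  }
  su <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(cc_raw = cc_raw, pl_raw = pl_raw,
         cc_norm = cc_raw / su$cc, pl_norm = pl_raw / su$pl,
         n_surrogates = as.integer(n_surrogates)),
    class = "weighted_graph_metrics"
  )
}

#' @export
print.weighted_graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<weighted_graph_metrics> CC %.4f (norm %.3f), PL %.4f (norm %.3f), %d surrogates\n",
    x$cc_raw, x$cc_norm, x$pl_raw, x$pl_norm, x$n_surrogates))
  invisible(x)
}
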