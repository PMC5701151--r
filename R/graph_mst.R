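# Spanning-tree backbone of the connectivity network. With similarity weights
# (PLI), minimizing total link cost (inverse connectivity) is the same as
# maximizing total weight, so the tree is built by Kruskal's algorithm on
# descending weights with union-find cycle rejection. Tree metrics: leaf
# number/fraction, betweenness centrality, and tree hierarchy
# TH = LN / (2 * (N - 1) * BC_max), which is 0.5 exactly for a star and tends
# to 0 for a long line.

#' Maximum-weight spanning tree (Kruskal)
#'
#' Edges are taken in order of decreasing weight (ties broken by ascending
#' node-index pair) and accepted unless they close a cycle, until the `N`
#' nodes are connected by `N - 1` edges. Zero weights are treated as absent
#' edges; a disconnected input is an error naming the component sizes.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @return a `spanning_tree` object: `n_nodes`, `edges` (`(N-1) x 2` matrix),
#'   `weights`, `total_weight`, `degree`, `adjacency` and `tie_broken` (TRUE
#'   when duplicate weights made the tie rule bite, i.e. the tree may be
#'   non-unique).
#' @export
maximum_spanning_tree <- function(cm) {
  W <- conn_as_matrix(cm)
  N <- nrow(W)
  pairs <- upper_pairs(N)
  w <- W[pairs]
  present <- w > 0
  pairs <- pairs[present, , drop = FALSE]
  w <- w[present]
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sel <- integer(0)
  for (e in ord) {
    ri <- find(pairs[e, 1L]); rj <- find(pairs[e, 2L])
    if (ri != rj) {
      parent[ri] <- rj
      sel <- c(sel, e)
      if (length(sel) == N - 1L) break
    }
  }
  if (length(sel) < N - 1L) {
    comp <- vapply(seq_len(N), find, 0L)
    sizes <- sort(table(comp), decreasing = TRUE)
    stop(sprintf(
      "graph is disconnected (%d components, sizes %s): no spanning tree",
      length(sizes), paste(sizes, collapse = ", ")))
  }
  edges <- pairs[sel, , drop = FALSE]
  ew <- w[sel]
  adj <- matrix(FALSE, N, N)
  adj[edges] <- TRUE
  adj <- adj | t(adj)
  structure(
    list(n_nodes = N, edges = edges, weights = ew, total_weight = sum(ew),
         degree = rowSums(adj), adjacency = adj,
         tie_broken = anyDuplicated(w) > 0L),
    class = "spanning_tree"
  )
}

#' Build a spanning tree from an explicit edge list
#'
#' Mainly for constructing reference topologies (stars, lines) directly.
#'
#' @param n_nodes node count.
#' @param edges `(n_nodes - 1) x 2` matrix of node pairs.
#' @return a `spanning_tree` object.
#' @export
spanning_tree_from_edges <- function(n_nodes, edges) {
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2L, nrow(edges) == n_nodes - 1L,
            all(edges >= 1L), all(edges <= n_nodes),
            all(edges[, 1L] != edges[, 2L]))
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::components(g)$no != 1L) stop("edge list does not form a tree")
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges,
         weights = rep(1, nrow(edges)), total_weight = nrow(edges),
         degree = rowSums(adj), adjacency = adj, tie_broken = FALSE),
    class = "spanning_tree"
  )
}

#' @export
print.spanning_tree <- function(x, ...) {
  lm <- leaf_metrics(x)
  cat(sprintf("<spanning_tree> %d nodes, %d edges, %d leaves%s\n",
              x$n_nodes, nrow(x$edges), lm$leaf_number,
              if (x$tie_broken) " (weight ties broken by index)" else ""))
  invisible(x)
}

#' Leaf number and leaf fraction of a tree
#'
#' Leaves are degree-1 nodes; the leaf number of a tree on `N` nodes ranges
#' from 2 (line) to `N - 1` (star). The fraction divides by the node count by
#' default (`denominator = "nodes"`), with the edge-count variant
#' (`"edges"`) available.
#'
#' @param tree a `spanning_tree`.
#' @param denominator `"nodes"` (leaf_number / N, default) or `"edges"`
#'   (leaf_number / (N - 1)).
#' @return list with `leaf_number` and `leaf_fraction`.
#' @export
leaf_metrics <- function(tree, denominator = c("nodes", "edges")) {
  stopifnot(inherits(tree, "spanning_tree"))
  denominator <- match.arg(denominator)
  ln <- sum(tree$degree == 1L)
  den <- if (denominator == "nodes") tree$n_nodes else tree$n_nodes - 1L
  list(leaf_number = ln, leaf_fraction = ln / den)
}

# Per-node normalized betweenness centrality on a tree: the fraction of the
# (N-1)(N-2)/2 node pairs (excluding the node itself) whose unique tree path
# passes through the node. Computed from subtree sizes: removing node v
# splits the tree into components c_1..c_d, and the pair count through v is
# (T^2 - sum c_k^2) / 2 with T = N - 1.
tree_betweenness <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  N <- tree$n_nodes
  if (N < 3L) stop("betweenness centrality needs at least 3 nodes")
  nbr <- lapply(seq_len(N), function(i) which(tree$adjacency[i, ]))
  # iterative DFS from node 1: order and parents
  parent <- integer(N); order <- integer(N)
  visited <- logical(N)
  stack <- 1L; visited[1L] <- TRUE; k <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- v
    for (u in nbr[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  size <- rep(1L, N)
  for (v in rev(order)) {
    if (parent[v] != 0L) size[parent[v]] <- size[parent[v]] + size[v]
  }
  total <- N - 1L
  bc <- numeric(N)
  for (v in seq_len(N)) {
    comps <- size[setdiff(nbr[[v]], parent[v])]
    if (parent[v] != 0L) comps <- c(comps, total - sum(comps))
    bc[v] <- (total^2 - sum(comps^2)) / 2
  }
  bc / (total * (N - 2L) / 2)
}

#' Maximum betweenness centrality of a tree
#'
#' @param tree a `spanning_tree` with at least 3 nodes.
#' @return scalar in `[0, 1]`; 1 for the hub of a star.
#' @export
betweenness_max <- function(tree) {
  max(tree_betweenness(tree))
}

#' Tree hierarchy
#'
#' `TH = LN / (2 * (N - 1) * BC_max)`, balancing integration (many leaves)
#' against hub overload (high maximum betweenness): exactly 0.5 for a star,
#' tending to 0 for a long line, and in `(0, 1]` in general.
#'
#' @param tree a `spanning_tree` with at least 3 nodes.
#' @return scalar in `(0, 1]`.
#' @export
tree_hierarchy <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  if (tree$n_nodes < 3L) stop("tree hierarchy needs at least 3 nodes")
  ln <- leaf_metrics(tree)$leaf_number
  ln / (2 * (tree$n_nodes - 1L) * betweenness_max(tree))
}

#' All spanning-tree metrics of a connectivity matrix
#'
#' Convenience wrapper: builds the maximum spanning tree and returns its
#' summary metrics.
#'
#' @param cm a `connectivity_matrix` or symmetric non-negative matrix.
#' @return an `mst_metrics` object: `leaf_number`, `leaf_fraction`, `bc_max`,
#'   `tree_hierarchy`, `tie_broken`.
#' @export
mst_metrics <- function(cm) {
  tree <- maximum_spanning_tree(cm)
  lm <- leaf_metrics(tree)
  structure(
    list(leaf_number = lm$leaf_number, leaf_fraction = lm$leaf_fraction,
         bc_max = betweenness_max(tree),
         tree_hierarchy = tree_hierarchy(tree),
         tie_broken = tree$tie_broken),
    class = "mst_metrics"
  )
}

#' @export
print.mst_metrics <- function(x, ...) {
  cat(sprintf(
    "<mst_metrics> leaves %d (fraction %.3f), BC_max %.3f, hierarchy %.3f\n",
    x$leaf_number, x$leaf_fraction, x$bc_max, x$tree_hierarchy))
  invisible(x)
}
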