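# Independent brute-force oracles used to check the implementation, plus tiny
# fixture builders. These deliberately use naive loops / alternative
# algorithms, never the package's own code paths.

rand_sym <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Direct evaluation of PLI from two phase series: naive per-sample loop over
# sign of the wrapped difference.
oracle_pli_from_phases <- function(p1, p2) {
  s <- numeric(length(p1))
  for (k in seq_along(p1)) {
    d <- p1[k] - p2[k]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    s[k] <- sign(d)
  }
  abs(mean(s))
}

# Triple-loop weighted clustering (ordered neighbour pairs k != i, l != i, k).
oracle_weighted_cc <- function(W) {
  n <- nrow(W)
  cci <- numeric(n)
  for (i in 1:n) {
    num <- 0; den <- 0
    for (k in 1:n) for (l in 1:n) {
      if (k == i || l == i || l == k) next
      num <- num + W[i, k] * W[i, l] * W[k, l]
      den <- den + W[i, k] * W[i, l]
    }
    cci[i] <- if (den > 0) num / den else 0
  }
  mean(cci)
}

# Floyd-Warshall all-pairs shortest paths on a distance matrix (Inf = absent).
oracle_floyd <- function(D) {
  n <- nrow(D)
  L <- D
  diag(L) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (L[i, k] + L[k, j] < L[i, j]) L[i, j] <- L[i, k] + L[k, j]
  }
  L
}

# Harmonic-mean aggregation over distinct pairs (1/Inf = 0).
oracle_harmonic_pl <- function(L) {
  1 / mean(1 / L[upper.tri(L)])
}

# Fraction-of-neighbour-edges binary clustering by explicit counting.
oracle_binary_cc <- function(A) {
  n <- nrow(A)
  cci <- numeric(n)
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] == 1) e <- e + 1
    }
    cci[i] <- e / (k * (k - 1) / 2)
  }
  mean(cci)
}

# Decode a Pruefer sequence into the edge list of the labelled tree on
# n = length(seq) + 2 nodes.
prufer_edges <- function(sq, n) {
  degree <- rep(1L, n)
  for (s in sq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (s in sq) {
    leaf <- which(degree == 1L)[1L]
    k <- k + 1L
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

random_tree <- function(n, seed) {
  set.seed(seed)
  prufer_edges(sample.int(n, n - 2L, replace = TRUE), n)
}

# Normalized tree betweenness by explicit path enumeration: for every node
# pair, walk the unique tree path (BFS parents) and credit interior nodes.
oracle_tree_bc <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  path_between <- function(a, b) {
    parent <- rep(0L, n)
    visited <- rep(FALSE, n)
    queue <- a
    visited[a] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (v == b) break
      for (u in which(adj[v, ])) {
        if (!visited[u]) {
          visited[u] <- TRUE
          parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    p <- b
    path <- b
    while (p != a) {
      p <- parent[p]
      path <- c(p, path)
    }
    path
  }
  count <- numeric(n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    pth <- path_between(a, b)
    interior <- setdiff(pth, c(a, b))
    count[interior] <- count[interior] + 1
  }
  count / ((n - 1) * (n - 2) / 2)
}

star_edges <- function(n, hub = 1L) {
  cbind(hub, setdiff(seq_len(n), hub))
}

line_edges <- function(n) {
  cbind(1:(n - 1), 2:n)
}

# A weight matrix whose maximum spanning tree is a star around `hub`.
star_weighted_matrix <- function(n, hub = 1L, strong = 0.9, weak = 0.1) {
  W <- matrix(weak, n, n)
  W[hub, ] <- strong
  W[, hub] <- strong
  diag(W) <- 0
  W
}

make_recording <- function(data, fs = 250, ...) recording(data, sample_rate = fs, ...)

# FFT amplitude of an exact frequency bin.
fft_amp <- function(x, f, fs) {
  n <- length(x)
  bin <- round(f * n / fs) + 1L
  2 * Mod(stats::fft(x))[bin] / n
}

small_test_config <- function(n_per_group = 2, n_channels = 8, duration = 20,
                              strength = 0.9, effect = 0.5, fraction = 0.15,
                              seed = 1, band = "alpha") {
  bc <- list(list(strength = strength, lag = pi / 4, fraction = fraction))
  names(bc) <- band
  ge <- stats::setNames(effect, band)
  cohort_config(n_subjects_per_group = n_per_group, n_channels = n_channels,
                duration = duration, band_coupling = bc, group_effect = ge,
                seed = seed)
}
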