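# Internal numeric helpers shared across modules.

#' Wrap phase angles into (-pi, pi]
#' @param x numeric vector or matrix of angles in radians.
#' @return object of the same shape with every angle reduced modulo 2*pi into
#'   the half-open interval (-pi, pi].
#' @keywords internal
#' @noRd
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Zeroes the negative-frequency half of the spectrum (doubling the positive
#' half) so that `Arg()` of the result is the instantaneous phase and `Mod()`
#' the instantaneous amplitude.
#' @param x real numeric vector.
#' @return complex vector of `length(x)`.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for the analytic signal")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Extract the square numeric matrix from a connectivity_matrix or accept a
# plain symmetric matrix; validates symmetry and non-negativity.
conn_as_matrix <- function(x, min_nodes = 2L) {
  W <- if (inherits(x, "connectivity_matrix")) x$matrix else x
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    stop("expected a square numeric matrix or a connectivity_matrix")
  }
  if (nrow(W) < min_nodes) {
    stop(sprintf("need at least %d nodes, got %d", min_nodes, nrow(W)))
  }
  if (any(!is.finite(W))) stop("matrix entries must be finite")
  if (any(W < 0)) stop("matrix entries must be non-negative")
  if (max(abs(W - t(W))) > 1e-10) stop("matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix
# ordered by (i, j) ascending.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
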