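# Phase-lag-index functional connectivity. PLI between two signals is the
# absolute mean sign of their wrapped instantaneous phase difference:
# PLI = |< sign(delta_phi(t_k)) >|, in [0, 1]. It is 1 for a perfectly
# consistent nonzero lag and 0 for no coupling or coupling at a lag centred on
# 0 mod pi (which makes it insensitive to volume-conduction-like zero-lag
# mixing).

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (frequency-domain Hilbert construction).
#'
#' @param x real numeric vector; must not be all zero.
#' @return numeric vector of phases in (-pi, pi], same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 250)
#' phi <- instantaneous_phase(cos(2 * pi * 10 * t))
#' @export
instantaneous_phase <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(!is.finite(x))) stop("x must be finite")
  if (all(x == 0)) stop("phase of the all-zero signal is undefined")
  Arg(analytic_signal(x))
}

#' Phase lag index between two signals
#'
#' `PLI = |mean(sign(delta_phi))|` with the phase difference wrapped into
#' `(-pi, pi]` and the three-valued sign convention (`sign(0) = 0`), so that
#' identical signals give exactly 0. Symmetric in its arguments and invariant
#' under amplitude scaling.
#'
#' @param x,y real numeric vectors of equal length (>= 2 samples).
#' @return scalar in `[0, 1]`.
#' @examples
#' t <- seq(0, 5, by = 1 / 250)[1:1250]
#' pli(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t - pi / 4)) # 1: consistent lag
#' @export
pli <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  dphi <- instantaneous_phase(x) - instantaneous_phase(y)
  abs(mean(sign(wrap_phase(dphi))))
}

# PLI for all unordered channel pairs from a samples x channels phase matrix.
pli_matrix_from_phases <- function(P) {
  N <- ncol(P)
  M <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    D <- P[, (i + 1L):N, drop = FALSE] - P[, i]
    M[i, (i + 1L):N] <- abs(colMeans(sign(wrap_phase(D))))
  }
  M + t(M)
}

#' Averaged PLI connectivity matrix for one subject and band
#'
#' Computes the channels x channels PLI matrix within every segment and
#' averages the per-segment matrices arithmetically.
#'
#' @param seg_data a `segmented_band_data` object from [segment_recording()].
#' @return a `connectivity_matrix` object: list with `subject_id`, `band`,
#'   `matrix` (symmetric, zero diagonal, entries in `[0, 1]`) and
#'   `n_segments_averaged`.
#' @export
connectivity_matrix <- function(seg_data) {
  stopifnot(inherits(seg_data, "segmented_band_data"))
  segs <- seg_data$segments
  if (length(segs) == 0L) stop("no segments to average")
  N <- nrow(segs[[1L]])
  acc <- matrix(0, N, N)
  for (S in segs) {
    P <- apply(S, 1L, instantaneous_phase)  # samples x channels
    acc <- acc + pli_matrix_from_phases(P)
  }
  M <- acc / length(segs)
  dimnames(M) <- list(rownames(segs[[1L]]), rownames(segs[[1L]]))
  structure(
    list(subject_id = seg_data$subject_id, band = seg_data$band,
         matrix = M, n_segments_averaged = length(segs)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> subject %s, band %s: %d x %d PLI, mean %.3f (%d segments)\n",
    x$subject_id, x$band, nrow(x$matrix), ncol(x$matrix),
    global_mean_pli(x), x$n_segments_averaged))
  invisible(x)
}

#' Global mean PLI
#'
#' Mean over all `N(N-1)/2` distinct channel pairs of a connectivity matrix.
#'
#' @param cm a `connectivity_matrix` or plain symmetric matrix.
#' @return scalar mean connectivity.
#' @export
global_mean_pli <- function(cm) {
  W <- conn_as_matrix(cm)
  mean(W[upper.tri(W)])
}

#' Edgewise two-group comparison of connectivity
#'
#' Per-edge two-sample t-test across subjects with Benjamini-Hochberg FDR
#' control, as used for connection-level group difference maps.
#'
#' @param group1,group2 lists of `connectivity_matrix` objects (>= 2 subjects
#'   per group), all on the same channel set.
#' @param alpha FDR level for flagging edges (default 0.05).
#' @param welch use the Welch test instead of pooled-variance Student.
#' @return an `edgewise_comparison` object: matrices `t_stat`, `p_raw`,
#'   `p_fdr`, `sign` (sign of group1 - group2 mean difference), a logical
#'   `significant` matrix, a data frame `edges` of significant edges, and
#'   `degenerate` (logical matrix of zero-variance edges, excluded from
#'   testing).
#' @export
edgewise_group_comparison <- function(group1, group2, alpha = 0.05,
                                      welch = FALSE) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  stack <- function(g) {
    mats <- lapply(g, conn_as_matrix)
    N <- nrow(mats[[1L]])
    stopifnot(all(vapply(mats, nrow, 0L) == N))
    ut <- upper.tri(mats[[1L]])
    list(N = N, vals = vapply(mats, function(m) m[ut], numeric(sum(ut))))
  }
  s1 <- stack(group1); s2 <- stack(group2)
  if (s1$N != s2$N) stop("groups must share the channel set")
  N <- s1$N
  n1 <- ncol(s1$vals); n2 <- ncol(s2$vals)
  m1 <- rowMeans(s1$vals); m2 <- rowMeans(s2$vals)
  v1 <- apply(s1$vals, 1L, stats::var); v2 <- apply(s2$vals, 1L, stats::var)
  degen <- (v1 + v2) == 0
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- ifelse(degen, NA_real_, (m1 - m2) / se)
  p <- 2 * stats::pt(-abs(tval), df)
  p_fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  to_mat <- function(v) {
    M <- matrix(NA_real_, N, N)
    M[upper.tri(M)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  idx <- which(upper.tri(diag(N)), arr.ind = TRUE)
  sig <- ok & p_fdr < alpha
  edges <- data.frame(i = idx[sig, 1L], j = idx[sig, 2L],
                      t = tval[sig], p_raw = p[sig], p_fdr = p_fdr[sig],
                      sign = sign(m1 - m2)[sig])
  structure(
    list(t_stat = to_mat(tval), p_raw = to_mat(p), p_fdr = to_mat(p_fdr),
         sign = to_mat(sign(m1 - m2)), significant = to_mat(as.numeric(sig)) == 1,
         edges = edges[order(edges$p_fdr), , drop = FALSE],
         degenerate = to_mat(as.numeric(degen)) == 1, alpha = alpha),
    class = "edgewise_comparison"
  )
}

#' @export
print.edgewise_comparison <- function(x, ...) {
  cat(sprintf("<edgewise_comparison> %d edges significant at FDR %.2f\n",
              nrow(x$edges), x$alpha))
  invisible(x)
}
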