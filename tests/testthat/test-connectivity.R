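fs <- 250
tt <- (0:1249) / fs  # 5 s, integer cycle counts for 10 Hz

test_that("instantaneous phase advances at the signal frequency", {
  ph <- instantaneous_phase(cos(2 * pi * 10 * tt))
  # unwrap and regress: slope should be 2*pi*10 rad/s within 1%
  unwrapped <- cumsum(c(ph[1], diff(ph) - 2 * pi * round(diff(ph) / (2 * pi))))
  slope <- stats::coef(stats::lm(unwrapped ~ tt))[2]
  expect_equal(unname(slope), 2 * pi * 10, tolerance = 0.01)

  # quadrature pair: constant pi/2 difference away from the edges
  ps <- instantaneous_phase(sin(2 * pi * 10 * tt))
  pc <- instantaneous_phase(cos(2 * pi * 10 * tt))
  d <- (pc - ps)[100:1150]
  dd <- abs(d - pi / 2) %% (2 * pi)
  expect_true(all(pmin(dd, 2 * pi - dd) < 0.05))

  # sign flip = phase difference pi
  x <- cos(2 * pi * 10 * tt)
  dneg <- instantaneous_phase(x) - instantaneous_phase(-x)
  expect_true(all(abs(abs(dneg[100:1150]) - pi) < 1e-6))

  expect_error(instantaneous_phase(rep(0, 100)), "undefined")
})

test_that("PLI hits its analytic limits and matches the direct formula", {
  x <- cos(2 * pi * 10 * tt)
  y <- cos(2 * pi * 10 * tt - pi / 4)
  expect_equal(pli(x, y), 1)        # perfect phase locking at nonzero lag
  expect_equal(pli(x, x), 0)        # zero lag: sign(0) convention gives 0
  expect_error(pli(x, y[-1]), "equal length")

  set.seed(3)
  a <- rnorm(1e4); b <- rnorm(1e4)
  v <- pli(a, b)
  expect_lt(v, 0.05)                # independent signals decorrelate
  expect_equal(v, oracle_pli_from_phases(instantaneous_phase(a),
                                         instantaneous_phase(b)))
})

test_that("PLI is symmetric, amplitude-invariant and bounded", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(400); y <- rnorm(400)
    v <- pli(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(pli(y, x), v)
    expect_equal(pli(3.7 * x, 0.2 * y), v)
  }
  # lag-pi/2 coupled sinusoids lock perfectly for any whole-cycle segment
  for (ncyc in c(1, 3, 10)) {
    ts <- seq(0, ncyc / 10, length.out = ncyc * 25 + 1)[-(ncyc * 25 + 1)]
    expect_equal(pli(cos(2 * pi * 10 * ts), cos(2 * pi * 10 * ts - pi / 2)), 1)
  }
})

test_that("connectivity matrix averages per-segment PLI correctly", {
  make_seg <- function(segs) {
    structure(list(subject_id = "s", band = "alpha", sample_rate = fs,
                   segment_length = 5, segments = segs),
              class = "segmented_band_data")
  }
  set.seed(21)
  S1 <- matrix(rnorm(3 * 500), nrow = 3)
  S2 <- matrix(rnorm(3 * 500), nrow = 3)

  one <- connectivity_matrix(make_seg(list(S1)))
  expect_equal(one$n_segments_averaged, 1)
  # matches direct pairwise pli() on the same segment
  expect_equal(one$matrix[1, 2], pli(S1[1, ], S1[2, ]), ignore_attr = TRUE)

  two_same <- connectivity_matrix(make_seg(list(S1, S1)))
  expect_equal(two_same$matrix, one$matrix)

  # entrywise mean of per-segment brute-force matrices
  both <- connectivity_matrix(make_seg(list(S1, S2)))
  brute <- matrix(0, 3, 3)
  for (S in list(S1, S2)) {
    P <- apply(S, 1, instantaneous_phase)
    for (i in 1:2) for (j in (i + 1):3) {
      brute[i, j] <- brute[i, j] + oracle_pli_from_phases(P[, i], P[, j])
    }
  }
  brute <- (brute + t(brute)) / 2
  expect_equal(both$matrix, brute, ignore_attr = TRUE)

  # symmetry and zero diagonal invariants
  expect_equal(both$matrix, t(both$matrix))
  expect_equal(diag(both$matrix), rep(0, 3), ignore_attr = TRUE)
  expect_error(connectivity_matrix(make_seg(list())), "no segments")
})

test_that("global mean PLI averages the distinct pairs", {
  W <- matrix(0.3, 4, 4); diag(W) <- 0
  expect_equal(global_mean_pli(W), 0.3)
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.1
  W3[1, 3] <- W3[3, 1] <- 0.2
  W3[2, 3] <- W3[3, 2] <- 0.3
  expect_equal(global_mean_pli(W3), 0.2)
  W6 <- rand_sym(6, seed = 5)
  acc <- 0
  for (i in 1:5) for (j in (i + 1):6) acc <- acc + W6[i, j]
  expect_equal(global_mean_pli(W6), acc / 15)
})

test_that("edgewise comparison finds no edges under the null and matches hand t-tests", {
  set.seed(9)
  mats <- lapply(1:4, function(i) {
    structure(list(subject_id = paste0("s", i), band = "alpha",
                   matrix = rand_sym(5, seed = i), n_segments_averaged = 1),
              class = "connectivity_matrix")
  })
  same <- edgewise_group_comparison(mats, mats)
  expect_equal(nrow(same$edges), 0)

  # two edges with hand-entered per-subject values
  v1 <- c(0.50, 0.55, 0.60)   # group 1, edge (1,2)
  v2 <- c(0.20, 0.25, 0.30)   # group 2, edge (1,2)
  mk <- function(a, b) {
    W <- matrix(0.4, 3, 3); diag(W) <- 0
    W[1, 2] <- W[2, 1] <- a
    W[1, 3] <- W[3, 1] <- b
    W
  }
  g1 <- lapply(1:3, function(i) mk(v1[i], 0.40 + 0.01 * i))
  g2 <- lapply(1:3, function(i) mk(v2[i], 0.40 + 0.01 * i))
  cmp <- edgewise_group_comparison(g1, g2)
  hand <- stats::t.test(v1, v2, var.equal = TRUE)
  expect_equal(cmp$t_stat[1, 2], unname(hand$statistic))
  expect_equal(cmp$p_raw[1, 2], hand$p.value)
  expect_equal(cmp$sign[1, 2], 1)
  # edge (2,3) has zero variance in both groups: flagged, not crashed
  expect_true(cmp$degenerate[2, 3])
  expect_true(is.na(cmp$t_stat[2, 3]))
})
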