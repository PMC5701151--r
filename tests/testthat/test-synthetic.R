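test_that("cohort configuration validates its invariants", {
  expect_error(cohort_config(2, duration = 0), "duration")
  expect_error(cohort_config(2, sample_rate = -1), "sample_rate")
  expect_error(small_test_config(strength = 1.2), "strength")
  expect_error(small_test_config(effect = 0), "group_effect")
  expect_error(small_test_config(effect = 1.5), "group_effect")
  # a 0-mod-pi lag is invisible to PLI and must be rejected when coupling > 0
  expect_error(
    cohort_config(2, n_channels = 8, duration = 10,
                  band_coupling = list(alpha = list(strength = 0.5, lag = 0,
                                                    fraction = 0.1)),
                  group_effect = c(alpha = 0.5)),
    "0 mod pi")
  expect_error(
    cohort_config(2, n_channels = 8, duration = 10,
                  band_coupling = list(alpha = list(strength = 0.5, lag = pi,
                                                    fraction = 0.1)),
                  group_effect = c(alpha = 0.5)),
    "0 mod pi")
  # but a zero-strength band may carry any lag
  expect_silent(
    cohort_config(2, n_channels = 8, duration = 10,
                  band_coupling = list(alpha = list(strength = 0, lag = 0,
                                                    fraction = 0.1)),
                  group_effect = c(alpha = 1)))
})

test_that("generation is deterministic and produces well-formed recordings", {
  cfg <- small_test_config(n_per_group = 2, n_channels = 8, duration = 10,
                           seed = 4)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)   # bit-identical under the same seed

  expect_length(c1, 4)
  expect_equal(vapply(c1, `[[`, 0L, "group"), c(1L, 1L, 2L, 2L))
  for (rec in c1) {
    expect_equal(dim(rec$data), c(8, 2500))
    expect_true(all(is.finite(rec$data)))
  }
  lay <- attr(c1, "layout")$alpha
  expect_true(all(lay$strength <= 0.9 & lay$strength >= 0.3))
  expect_true(all(lay$src != lay$tgt))

  # a different seed changes the data
  c3 <- generate_cohort(small_test_config(n_per_group = 2, n_channels = 8,
                                          duration = 10, seed = 5))
  expect_false(identical(c1[[1]]$data, c3[[1]]$data))
})

test_that("zero coupling produces near-independent channels", {
  cfg <- small_test_config(n_per_group = 1, n_channels = 8, duration = 20,
                           strength = 0, effect = 1, seed = 6)
  coh <- generate_cohort(cfg)
  cm <- subject_connectivity(coh[[1]], "alpha")
  expect_lt(global_mean_pli(cm), 0.3)  # only the finite-sample noise floor
})

test_that("coupled-pair PLI is monotone in coupling strength", {
  coupled_pli <- function(strength, seed) {
    cfg <- small_test_config(n_per_group = 1, n_channels = 12, duration = 20,
                             strength = strength, effect = 1, seed = seed)
    coh <- generate_cohort(cfg)
    lay <- attr(coh, "layout")$alpha
    cm <- subject_connectivity(coh[[1]], "alpha")
    mean(cm$matrix[cbind(lay$src, lay$tgt)])
  }
  # Monte-Carlo sd of the statistic at the middle strength, over 10 seeds
  reps <- vapply(1:10, function(s) coupled_pli(0.6, 300 + s), 0)
  tol <- stats::sd(reps)
  vals <- vapply(c(0.3, 0.6, 0.9), coupled_pli, 0, seed = 17)
  expect_gt(vals[2] - vals[1], -tol)
  expect_gt(vals[3] - vals[2], -tol)
  expect_gt(vals[3] - vals[1], tol)  # and clearly increasing overall
})

test_that("coupling injected in alpha leaves the beta band at chance level", {
  pvals <- numeric(10)
  for (s in 1:10) {
    cfg <- small_test_config(n_per_group = 4, n_channels = 12, duration = 20,
                             strength = 0.9, effect = 0.5, seed = 400 + s,
                             band = "alpha")
    coh <- generate_cohort(cfg)
    beta_mean <- vapply(coh, function(rec) {
      global_mean_pli(subject_connectivity(rec, "beta"))
    }, 0)
    grp <- vapply(coh, `[[`, 0L, "group")
    pvals[s] <- group_ttest(beta_mean[grp == 1], beta_mean[grp == 2])$p
  }
  expect_lte(sum(pvals < 0.01), 1)  # no systematic beta-band group effect
})

test_that("cohorts survive a plain-text round trip", {
  cfg <- small_test_config(n_per_group = 1, n_channels = 4, duration = 4,
                           seed = 9)
  coh <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$data, coh[[1]]$data, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back[[2]]$group, 2L)
  unlink(dir, recursive = TRUE)
})
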