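# Group-comparison statistics: Shapiro-Wilk normality screening (advisory),
# independent two-sample t-tests per network measure and band, and Bonferroni
# correction within measure families. Significance tiers follow corrected p:
# significant (p < 0.01), marginal (0.01 <= p < 0.05), ns.

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @return list with `statistic` and `p_value`.
#' @export
normality_screen <- function(values) {
  if (length(values) < 3L) stop("normality screen needs n >= 3")
  if (stats::sd(values) == 0) stop("normality screen undefined for a constant vector")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Independent two-sample t-test
#'
#' Pooled-variance (Student) by default; Welch optionally.
#'
#' @param group1,group2 numeric vectors, n >= 2 each.
#' @param welch use the Welch (unequal-variance) test.
#' @return list with `t`, `p` (two-sided), `df`, and the group means.
#' @examples
#' group_ttest(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, p = 0.0214
#' @export
group_ttest <- function(group1, group2, welch = FALSE) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  if (stats::var(group1) + stats::var(group2) == 0) {
    stop("zero variance in both groups: t-test undefined")
  }
  tt <- stats::t.test(group1, group2, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean1 = mean(group1), mean2 = mean(group2))
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of raw p values.
#' @param n_comparisons family size; must be at least `length(p_values)`.
#' @return corrected p values, `min(1, p * n_comparisons)`.
#' @examples
#' bonferroni(c(0.004, 0.9), 2)
#' @export
bonferroni <- function(p_values, n_comparisons) {
  if (n_comparisons < length(p_values)) {
    stop("n_comparisons must be at least the number of p values")
  }
  pmin(1, p_values * n_comparisons)
}

sig_tier <- function(p_corrected, alpha = 0.01, marginal = 0.05) {
  ifelse(p_corrected < alpha, "significant",
         ifelse(p_corrected < marginal, "marginal", "ns"))
}

# Family size for Bonferroni, per measure. Within each band: the two weighted
# measures form one family, the two tree measures another; the binary sweep is
# corrected for its two measures times the number of densities; the global
# mean PLI is corrected across the analysed bands.
family_size <- function(measure, n_bands, n_densities) {
  switch(measure,
         mean_pli = n_bands,
         cc_norm = 2L, pl_norm = 2L,
         leaf_fraction = 2L, tree_hierarchy = 2L,
         binary_cc = 2L * n_densities, binary_pl = 2L * n_densities,
         stop(sprintf("unknown measure '%s'", measure)))
}

#' Full two-group comparison over a metrics table
#'
#' Runs an independent t-test for every measure x band (x density)
#' combination, applies the Bonferroni correction within the measure's family,
#' and attaches a Shapiro-Wilk normality screen per group as an attribute.
#'
#' @param metrics tidy per-subject metrics data frame with columns `subject`,
#'   `group`, `band`, `measure`, `density` (NA for density-free measures) and
#'   `value`, as produced by [analyze_cohort()].
#' @param alpha significance level on corrected p values (default 0.01;
#'   0.01-0.05 is reported as marginal).
#' @param welch use Welch rather than pooled-variance t-tests.
#' @return a `group_comparison` data frame: one row per comparison with
#'   `band`, `measure`, `density`, group means, `t_stat`, `p_raw`,
#'   `p_corrected`, `n_comparisons` and `tier` (`"significant"`,
#'   `"marginal"`, `"ns"`, or `"degenerate"` when both groups have zero
#'   variance, as binary path length does at high densities). Normality
#'   screen results are in `attr(, "normality")`.
#' @export
run_full_comparison <- function(metrics, alpha = 0.01, welch = FALSE) {
  need <- c("subject", "group", "band", "measure", "density", "value")
  stopifnot(all(need %in% names(metrics)))
  subjects <- unique(metrics[, c("subject", "group")])
  combos <- unique(metrics[, c("band", "measure", "density")])
  n_bands <- length(unique(metrics$band))
  dens <- unique(metrics$density[!is.na(metrics$density)])
  n_densities <- max(1L, length(dens))
  rows <- vector("list", nrow(combos))
  norm_rows <- list()
  for (r in seq_len(nrow(combos))) {
    sel <- metrics$band == combos$band[r] &
      metrics$measure == combos$measure[r] &
      (is.na(combos$density[r]) |
         (!is.na(metrics$density) & metrics$density == combos$density[r]))
    if (is.na(combos$density[r])) sel <- sel & is.na(metrics$density)
    sub <- metrics[sel, , drop = FALSE]
    miss <- setdiff(subjects$subject, sub$subject)
    if (length(miss) > 0L) {
      stop(sprintf("missing subjects for %s/%s: %s", combos$band[r],
                   combos$measure[r], paste(miss, collapse = ", ")))
    }
    g1 <- sub$value[sub$group == 1L]
    g2 <- sub$value[sub$group == 2L]
    nfam <- family_size(combos$measure[r], n_bands, n_densities)
    if (stats::var(g1) + stats::var(g2) == 0) {
      # e.g. binary PL at high density, where the value is fully determined
      # by the fixed edge count: flagged, not crashed
      rows[[r]] <- data.frame(
        band = combos$band[r], measure = combos$measure[r],
        density = combos$density[r], mean_group1 = mean(g1),
        mean_group2 = mean(g2), t_stat = NA_real_, p_raw = NA_real_,
        p_corrected = NA_real_, n_comparisons = nfam,
        tier = "degenerate", stringsAsFactors = FALSE)
      next
    }
    tt <- group_ttest(g1, g2, welch = welch)
    pc <- bonferroni(tt$p, nfam)
    rows[[r]] <- data.frame(
      band = combos$band[r], measure = combos$measure[r],
      density = combos$density[r], mean_group1 = tt$mean1,
      mean_group2 = tt$mean2, t_stat = tt$t, p_raw = tt$p,
      p_corrected = pc, n_comparisons = nfam,
      tier = sig_tier(pc, alpha = alpha), stringsAsFactors = FALSE)
    for (g in 1:2) {
      vals <- if (g == 1L) g1 else g2
      sw <- if (length(vals) >= 3L && stats::sd(vals) > 0) {
        normality_screen(vals)
      } else list(statistic = NA_real_, p_value = NA_real_)
      norm_rows[[length(norm_rows) + 1L]] <- data.frame(
        band = combos$band[r], measure = combos$measure[r],
        density = combos$density[r], group = g,
        shapiro_w = sw$statistic, shapiro_p = sw$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$band, out$measure, out$density), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "normality") <- do.call(rbind, norm_rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Two-group network comparison (%d tests, alpha = %g, Bonferroni within families)\n",
              nrow(x), attr(x, "alpha") %||% 0.01))
  df <- as.data.frame(x)
  df$tier <- format(df$tier)
  print.data.frame(df, digits = digits, row.names = FALSE)
  invisible(x)
}
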