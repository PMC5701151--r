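# End-to-end orchestration: preprocessing chain -> per-band PLI connectivity
# -> weighted / binary / tree topology metrics per subject -> two-group
# statistics.

#' Per-subject, per-band network metrics from a connectivity matrix
#'
#' @param cm a `connectivity_matrix`.
#' @param densities link densities for the binary sweep (default the 15-point
#'   grid 0.2..0.9 step 0.05); `NULL` skips the binary analysis.
#' @param n_surrogates surrogate ensemble size for weighted-graph
#'   normalization; `0` skips it.
#' @param seed optional seed for the surrogate reshuffling.
#' @return tidy data frame with columns `subject`, `band`, `measure`,
#'   `density`, `value`.
#' @export
network_metrics <- function(cm, densities = seq(0.2, 0.9, by = 0.05),
                            n_surrogates = 100L, seed = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  rows <- list(
    data.frame(measure = "mean_pli", density = NA_real_,
               value = global_mean_pli(cm))
  )
  if (n_surrogates > 0L) {
    wg <- surrogate_normalize(cm, n_surrogates = n_surrogates, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = c("cc_norm", "pl_norm"), density = NA_real_,
      value = c(wg$cc_norm, wg$pl_norm))
  }
  if (!is.null(densities)) {
    sweep_df <- density_sweep(cm, densities)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = rep(c("binary_cc", "binary_pl"), each = nrow(sweep_df)),
      density = rep(sweep_df$density, 2L),
      value = c(sweep_df$cc, sweep_df$pl))
  }
  mm <- mst_metrics(cm)
  rows[[length(rows) + 1L]] <- data.frame(
    measure = c("leaf_fraction", "tree_hierarchy"), density = NA_real_,
    value = c(mm$leaf_fraction, mm$tree_hierarchy))
  out <- do.call(rbind, rows)
  out$subject <- cm$subject_id
  out$band <- cm$band
  out[, c("subject", "band", "measure", "density", "value")]
}

#' PLI connectivity matrix of one recording in one band
#'
#' Band-pass filters, segments and averages per-segment PLI matrices.
#'
#' @param rec a [recording()].
#' @param band a [band_definition()] or default band name.
#' @param segment_length segment length in seconds (default 5).
#' @return a `connectivity_matrix`.
#' @export
subject_connectivity <- function(rec, band, segment_length = 5) {
  connectivity_matrix(segment_recording(bandpass(rec, band), segment_length))
}

#' Run the full brain-network group analysis on a cohort
#'
#' For every subject and band: (optional re-reference, downsample and notch)
#' -> zero-phase band-pass -> 5-s segmentation -> averaged PLI connectivity
#' matrix -> global mean PLI, surrogate-normalized weighted clustering and
#' path length, binary clustering/path length over the link-density sweep,
#' and spanning-tree leaf fraction and tree hierarchy. The per-subject
#' metrics are then compared between groups with independent t-tests and
#' Bonferroni correction within measure families.
#'
#' @param cohort list of [recording()] objects (e.g. from
#'   [generate_cohort()] or [read_cohort()]); both groups must be present.
#' @param bands character vector of default band names, or list of
#'   [band_definition()] objects.
#' @param densities link-density grid for the binary analysis (default the
#'   15-point grid); `NULL` skips it.
#' @param segment_length PLI segment length in seconds.
#' @param n_surrogates surrogate count for weighted normalization (default
#'   100); `0` skips the weighted analysis.
#' @param reference_channels optional labels for re-referencing.
#' @param target_rate optional downsampling target in Hz.
#' @param notch_freq optional line-noise notch frequency in Hz.
#' @param alpha significance level on corrected p values.
#' @param welch use Welch t-tests.
#' @param seed seed for the surrogate reshuffling streams.
#' @return a `bna_analysis` object: list with `metrics` (tidy per-subject
#'   table), `comparisons` ([run_full_comparison()] output), `connectivity`
#'   (list of per-subject lists of `connectivity_matrix` by band), `bands`,
#'   `densities`, `n_subjects`.
#' @export
analyze_cohort <- function(cohort,
                           bands = c("delta", "theta", "alpha", "beta", "gamma"),
                           densities = seq(0.2, 0.9, by = 0.05),
                           segment_length = 5,
                           n_surrogates = 100L,
                           reference_channels = NULL,
                           target_rate = NULL,
                           notch_freq = NULL,
                           alpha = 0.01,
                           welch = FALSE,
                           seed = 1L) {
  stopifnot(is.list(cohort), length(cohort) >= 4L)
  stopifnot(all(vapply(cohort, inherits, TRUE, "recording")))
  groups <- vapply(cohort, `[[`, 0L, "group")
  if (!all(1:2 %in% groups)) stop("cohort must contain both groups")
  band_list <- lapply(bands, resolve_band)
  names(band_list) <- vapply(band_list, `[[`, "", "name")
  metrics <- list()
  conn <- list()
  for (si in seq_along(cohort)) {
    rec <- cohort[[si]]
    if (!is.null(reference_channels)) rec <- rereference(rec, reference_channels)
    if (!is.null(target_rate)) rec <- downsample(rec, target_rate)
    if (!is.null(notch_freq)) rec <- notch_filter(rec, notch_freq)
    conn[[rec$subject_id]] <- list()
    for (bi in seq_along(band_list)) {
      cmat <- subject_connectivity(rec, band_list[[bi]], segment_length)
      conn[[rec$subject_id]][[band_list[[bi]]$name]] <- cmat
      m <- network_metrics(cmat, densities = densities,
                           n_surrogates = n_surrogates,
                           seed = seed + 1000L * si + bi)
      m$group <- rec$group
      metrics[[length(metrics) + 1L]] <- m
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[, c("subject", "group", "band", "measure", "density", "value")]
  comparisons <- run_full_comparison(metrics, alpha = alpha, welch = welch)
  structure(
    list(metrics = metrics, comparisons = comparisons, connectivity = conn,
         bands = band_list, densities = densities,
         n_subjects = c(group1 = sum(groups == 1L), group2 = sum(groups == 2L))),
    class = "bna_analysis"
  )
}

#' @export
print.bna_analysis <- function(x, ...) {
  cat(sprintf(
    "<bna_analysis> %d + %d subjects, bands: %s\n",
    x$n_subjects[1L], x$n_subjects[2L],
    paste(names(x$bands), collapse = ", ")))
  cmp <- x$comparisons
  nsig <- sum(cmp$tier == "significant")
  nmar <- sum(cmp$tier == "marginal")
  cat(sprintf("  %d comparisons: %d significant, %d marginal\n",
              nrow(cmp), nsig, nmar))
  invisible(x)
}

#' @export
summary.bna_analysis <- function(object, ...) {
  cmp <- object$comparisons
  hits <- cmp[cmp$tier %in% c("significant", "marginal"), , drop = FALSE]
  cat(sprintf("Brain-network group analysis: %d + %d subjects\n",
              object$n_subjects[1L], object$n_subjects[2L]))
  if (nrow(hits) == 0L) {
    cat("No significant or marginal group differences.\n")
  } else {
    cat("Significant / marginal group differences (Bonferroni-corrected):\n")
    print.data.frame(as.data.frame(hits), digits = 4, row.names = FALSE)
  }
  invisible(hits)
}

#' Boxplot of one network measure by group
#'
#' @param x a `bna_analysis`.
#' @param measure measure name (e.g. `"mean_pli"`, `"leaf_fraction"`).
#' @param band band name.
#' @param density density for binary measures (nearest grid point used).
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the plotted data.
#' @export
plot.bna_analysis <- function(x, measure = "mean_pli",
                              band = names(x$bands)[1L],
                              density = NULL, ...) {
  m <- x$metrics
  sel <- m$measure == measure & m$band == band
  if (!is.null(density)) {
    d <- x$densities[which.min(abs(x$densities - density))]
    sel <- sel & !is.na(m$density) & m$density == d
  } else {
    sel <- sel & is.na(m$density)
  }
  sub <- m[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no metrics match the requested measure/band")
  graphics::boxplot(value ~ group, data = sub,
                    names = c("group 1", "group 2"),
                    ylab = measure, main = sprintf("%s (%s)", measure, band),
                    ...)
  invisible(sub)
}
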