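# Synthetic two-group multichannel cohorts with known, band-specific lagged
# phase coupling. Every channel carries an independent band-limited carrier in
# each configured band; a coupled (source -> target) pair mixes a time-shifted
# copy of the source carrier into the target at a per-pair coupling strength.
# The constant time shift gives the consistent nonzero phase lag that PLI
# rewards; group-2 subjects have their coupling strengths multiplied by a
# band-specific reduction factor.
#
# Two structural features emulate real PLI networks rather than a two-valued
# toy: per-pair strengths are spread over strength * U(1/3, 1) (real
# connectivity is graded), and sources are drawn with a bias towards a few hub
# channels (resting-state networks are hub-organised). Both matter for the
# tree metrics: a single uniform strength rescaled by a group factor preserves
# the rank order of all edge weights, and rank-preserving changes leave a
# maximum spanning tree untouched, so no tree-level group effect could exist.

#' Configure a synthetic cohort
#'
#' @param n_subjects_per_group subjects per group (two groups are generated).
#' @param n_channels number of channels (default 128).
#' @param sample_rate sampling rate in Hz (default 250).
#' @param duration recording length in seconds (default 60).
#' @param band_coupling named list, one entry per coupled band (names must be
#'   default band names). Each entry is a list with `strength` (base coupling
#'   mixing coefficient in `[0,1]`), `lag` (phase lag in radians at the band
#'   centre frequency; must not be congruent to 0 mod pi when `strength > 0`,
#'   since PLI is blind to 0/pi lags) and `fraction` (fraction of all channel
#'   pairs that are coupled, in `[0,1]`).
#' @param group_effect named numeric vector of multiplicative coupling
#'   reductions in `(0, 1]` applied to group 2; names must be coupled bands.
#' @param noise_sd standard deviation of the additive broadband noise.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param coupling_jitter length-2 range; each pair's strength is the base
#'   strength times a uniform draw from this range.
#' @param n_hubs number of hub (preferred source) channels; default
#'   `max(1, round(n_channels / 16))`.
#' @param hub_bias probability that a coupled pair originates from a hub.
#' @return a `cohort_config` object.
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 2, n_channels = 8, duration = 10,
#'                      seed = 1)
#' @export
cohort_config <- function(n_subjects_per_group,
                          n_channels = 128L,
                          sample_rate = 250,
                          duration = 60,
                          band_coupling = list(
                            theta = list(strength = 0.9, lag = pi / 4, fraction = 0.1),
                            alpha = list(strength = 0.9, lag = pi / 4, fraction = 0.1)
                          ),
                          group_effect = c(theta = 0.5, alpha = 0.5),
                          noise_sd = 1,
                          seed = 1L,
                          coupling_jitter = c(1 / 3, 1),
                          n_hubs = NULL,
                          hub_bias = 0.75) {
  stopifnot(n_subjects_per_group >= 1L, n_channels >= 2L)
  if (!(sample_rate > 0)) stop("sample_rate must be positive")
  if (!(duration > 0)) stop("duration must be positive")
  if (is.null(n_hubs)) n_hubs <- max(1L, round(n_channels / 16))
  stopifnot(n_hubs >= 1L, n_hubs <= n_channels,
            hub_bias >= 0, hub_bias <= 1,
            length(coupling_jitter) == 2L,
            all(coupling_jitter > 0), all(coupling_jitter <= 1),
            noise_sd >= 0)
  known <- names(default_bands())
  if (length(band_coupling) > 0L) {
    if (is.null(names(band_coupling)) || !all(names(band_coupling) %in% known)) {
      stop("band_coupling names must be default band names")
    }
    for (bn in names(band_coupling)) {
      bc <- band_coupling[[bn]]
      stopifnot(is.list(bc), all(c("strength", "lag", "fraction") %in% names(bc)))
      if (bc$strength < 0 || bc$strength > 1) {
        stop("coupling strength must be in [0, 1]")
      }
      if (bc$fraction < 0 || bc$fraction > 1) {
        stop("fraction_of_coupled_pairs must be in [0, 1]")
      }
      if (bc$strength > 0 && abs(sin(bc$lag)) < 1e-8) {
        stop(sprintf(
          "band '%s': phase lag congruent to 0 mod pi is undetectable by PLI", bn))
      }
    }
  }
  if (length(group_effect) > 0L) {
    if (is.null(names(group_effect)) ||
        !all(names(group_effect) %in% names(band_coupling))) {
      stop("group_effect names must be coupled band names")
    }
    if (any(group_effect <= 0) || any(group_effect > 1)) {
      stop("group_effect factors must be in (0, 1]")
    }
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_channels = as.integer(n_channels), sample_rate = sample_rate,
         duration = duration, band_coupling = band_coupling,
         group_effect = group_effect, noise_sd = noise_sd,
         seed = as.integer(seed), coupling_jitter = coupling_jitter,
         n_hubs = as.integer(n_hubs), hub_bias = hub_bias),
    class = "cohort_config"
  )
}

# Draw the coupled-pair layout for one band: hub-biased unique (source,
# target) pairs with per-pair strengths. Source and target roles are disjoint
# channel sets: a source keeps its own carrier undiluted, so the PLI of every
# coupled edge responds monotonically to a group-wise coupling reduction
# (cascaded couplings, where a target re-sources its diluted carrier, can
# invert that response). Called inside the cohort's seeded RNG stream.
draw_layout <- function(n_channels, hubs, bc, coupling_jitter, hub_bias) {
  n_pairs <- round(bc$fraction * n_channels * (n_channels - 1) / 2)
  src <- integer(0); tgt <- integer(0)
  seen <- character(0)
  guard <- 0L
  while (length(src) < n_pairs) {
    guard <- guard + 1L
    if (guard > 200L * n_pairs + 5000L) {
      stop("could not place coupled pairs; reduce fraction_of_coupled_pairs")
    }
    s <- if (stats::runif(1) < hub_bias) hubs[sample.int(length(hubs), 1L)]
         else sample.int(n_channels, 1L)
    t <- sample.int(n_channels, 1L)
    if (t == s || s %in% tgt || t %in% src) next
    key <- paste(min(s, t), max(s, t))
    if (key %in% seen) next
    seen <- c(seen, key)
    src <- c(src, s); tgt <- c(tgt, t)
  }
  data.frame(src = src, tgt = tgt,
             strength = bc$strength *
               stats::runif(n_pairs, coupling_jitter[1], coupling_jitter[2]))
}

# Band-limited unit-variance Gaussian carriers, one column per channel.
band_carriers <- function(n_len, n_channels, band, fs) {
  b <- fir_band_coef(band$low, band$high, fs, n_len)
  C <- matrix(stats::rnorm(n_len * n_channels), n_len, n_channels)
  C <- apply(C, 2L, zero_phase_fir, b = b)
  sds <- apply(C, 2L, stats::sd)
  sweep(C, 2L, pmax(sds, .Machine$double.eps), `/`)
}

#' Generate a synthetic two-group cohort
#'
#' Deterministic given the configuration (including its seed). Each recording
#' contains, for every configured band, band-limited carriers in all channels;
#' coupled pairs share a time-shifted copy of the source carrier mixed into
#' the target at the pair's coupling strength, on top of independent broadband
#' Gaussian noise. Group-2 subjects have coupling multiplied by the configured
#' reduction factor in affected bands.
#'
#' @param config a [cohort_config()].
#' @return list of [recording()] objects (group 1 first), with the ground
#'   truth attached as attributes: `layout` (per-band data frame of `src`,
#'   `tgt`, `strength`, `shift_samples`) and `hubs`.
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 1, n_channels = 6, duration = 10,
#'                      band_coupling = list(alpha = list(strength = 0.9,
#'                        lag = pi / 4, fraction = 0.2)),
#'                      group_effect = c(alpha = 0.5), seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$sample_rate
  n_len <- round(config$duration * fs)
  N <- config$n_channels
  bands <- default_bands()
  with_seed(config$seed, {
    hubs <- sample.int(N, config$n_hubs)
    layout <- list()
    for (bn in names(config$band_coupling)) {
      bc <- config$band_coupling[[bn]]
      band <- bands[[bn]]
      f_c <- (band$low + band$high) / 2
      shift <- max(1L, round(bc$lag / (2 * pi * f_c) * fs))
      lay <- draw_layout(N, hubs, bc, config$coupling_jitter, config$hub_bias)
      lay$shift_samples <- shift
      layout[[bn]] <- lay
    }
    n_total <- 2L * config$n_subjects_per_group
    groups <- rep(1:2, each = config$n_subjects_per_group)
    cohort <- vector("list", n_total)
    for (si in seq_len(n_total)) {
      g <- groups[si]
      X <- matrix(stats::rnorm(n_len * N, sd = config$noise_sd), n_len, N)
      for (bn in names(config$band_coupling)) {
        lay <- layout[[bn]]
        shift <- lay$shift_samples[1] %||% 0L
        if (nrow(lay) == 0L) shift <- 0L
        C <- band_carriers(n_len + shift, N, bands[[bn]], fs)
        own <- C[shift + seq_len(n_len), , drop = FALSE]
        B <- own
        if (nrow(lay) > 0L) {
          eff <- lay$strength *
            if (g == 2L && bn %in% names(config$group_effect))
              config$group_effect[[bn]] else 1
          # unit-variance mixing: the target keeps sqrt(1 - sum(s^2)) of its
          # own carrier, so band power is identical in both groups and only
          # the phase coupling differs
          incoming <- tapply(eff^2, lay$tgt, sum)
          for (ch in as.integer(names(incoming))) {
            B[, ch] <- sqrt(max(0, 1 - incoming[[as.character(ch)]])) * own[, ch]
          }
          for (p in seq_len(nrow(lay))) {
            # delayed copy of the source carrier: target lags source by `shift`
            B[, lay$tgt[p]] <- B[, lay$tgt[p]] + eff[p] * C[seq_len(n_len), lay$src[p]]
          }
        }
        X <- X + B
      }
      cohort[[si]] <- recording(t(X), sample_rate = fs,
                                subject_id = sprintf("g%d_s%02d", g,
                                                     (si - 1L) %% config$n_subjects_per_group + 1L),
                                group = g)
    }
    attr(cohort, "layout") <- layout
    attr(cohort, "hubs") <- hubs
    attr(cohort, "config") <- config
    cohort
  })
}
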