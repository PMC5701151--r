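# Signal-conditioning chain: re-reference -> downsample -> notch -> band-pass
# -> segment. All filtering is zero-phase FIR (windowed-sinc designed with
# signal::fir1, applied forward and backward by FFT convolution) because the
# phase lag index downstream is a pure phase statistic: any phase distortion
# here would bias it.

# Compensated single FIR pass: FFT convolution with the group delay removed.
fir_pass <- function(z, b) {
  nb <- length(b)
  d <- (nb - 1L) %/% 2L
  f <- signal::fftfilt(b, c(z, numeric(nb)))
  f[d + seq_along(z)]
}

# Zero-phase FIR filtering (forward-backward) with odd-symmetric edge padding
# to tame end transients. `b` must have odd length (even filter order).
zero_phase_fir <- function(x, b) {
  n <- length(x)
  nb <- length(b)
  if (nb %% 2L == 0L) stop("internal: FIR coefficient vector must have odd length")
  np <- min(n - 1L, 3L * nb %/% 2L)
  left <- 2 * x[1L] - x[seq(np + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - np)]
  y <- fir_pass(c(left, x, right), b)
  y <- rev(fir_pass(rev(y), b))
  y[np + seq_len(n)]
}

# Windowed-sinc band-pass coefficients. Transition bandwidth is 25% of the
# lower band edge (Hamming rule of thumb: order ~ 3.3 * fs / transition),
# capped so the filter stays well shorter than the signal.
fir_band_coef <- function(low, high, fs, n_len) {
  tbw <- 0.25 * low
  ord <- round(3.3 * fs / tbw)
  ord <- min(ord, (n_len - 1L) %/% 3L)
  ord <- max(ord - ord %% 2L, 10L)
  signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
}

apply_filter <- function(rec, b) {
  out <- rec
  out$data <- t(apply(rec$data, 1L, zero_phase_fir, b = b))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Re-reference a recording
#'
#' Subtracts the mean of the named reference channels (e.g. the two mastoid
#' sensors) from every channel.
#'
#' @param rec a [recording()].
#' @param reference_channels character vector of channel labels to average as
#'   the new reference.
#' @return the re-referenced [recording()].
#' @export
rereference <- function(rec, reference_channels) {
  stopifnot(inherits(rec, "recording"))
  missing_ch <- setdiff(reference_channels, rec$channel_labels)
  if (length(missing_ch) > 0L) {
    stop(sprintf("unknown reference channel(s): %s",
                 paste(missing_ch, collapse = ", ")))
  }
  ref <- colMeans(rec$data[reference_channels, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2L, ref, `-`)
  out
}

#' Downsample a recording
#'
#' Zero-phase FIR anti-alias filtering (cutoff at 80% of the new Nyquist
#' frequency) followed by decimation. The target rate must divide the current
#' sampling rate.
#'
#' @param rec a [recording()].
#' @param target_rate new sampling rate in Hz.
#' @return the downsampled [recording()].
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate
  if (target_rate > fs) stop("target_rate exceeds the current sample rate")
  if (target_rate == fs) return(rec)
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9) {
    stop("target_rate must divide the current sample rate")
  }
  q <- as.integer(round(q))
  cutoff <- 0.8 * (target_rate / 2)
  tbw <- 0.2 * (target_rate / 2)
  ord <- min(round(3.3 * fs / tbw), (ncol(rec$data) - 1L) %/% 3L)
  ord <- max(ord - ord %% 2L, 10L)
  b <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
  out <- apply_filter(rec, b)
  out$data <- out$data[, seq(1L, ncol(out$data), by = q), drop = FALSE]
  out$sample_rate <- target_rate
  out
}

#' Notch-filter line noise
#'
#' Zero-phase FIR band-stop around the line frequency (default 48-52 Hz).
#'
#' @param rec a [recording()].
#' @param freq notch centre frequency in Hz; must be below Nyquist.
#' @param width half-width of the stop band in Hz.
#' @return the filtered [recording()].
#' @export
notch_filter <- function(rec, freq = 50, width = 2) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate
  if (freq >= fs / 2) stop("notch frequency must be below Nyquist")
  ord <- min(round(3.3 * fs / 2), (ncol(rec$data) - 1L) %/% 3L)
  ord <- max(ord - ord %% 2L, 10L)
  b <- signal::fir1(ord, c(freq - width, freq + width) / (fs / 2), type = "stop")
  apply_filter(rec, b)
}

#' Band-pass filter a recording into one frequency band
#'
#' Zero-phase (forward-backward) windowed-sinc FIR filtering, so phase
#' relations between channels -- the quantity PLI measures -- are untouched.
#'
#' @param rec a [recording()].
#' @param band a [band_definition()] or the name of a default band.
#' @return the band-limited [recording()], with a `band` field recording the
#'   band name.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "recording"))
  band <- resolve_band(band)
  if (band$high >= rec$sample_rate / 2) {
    stop("band upper edge must be below Nyquist")
  }
  b <- fir_band_coef(band$low, band$high, rec$sample_rate, ncol(rec$data))
  out <- apply_filter(rec, b)
  out$band <- band$name
  out
}

#' Cut a recording into non-overlapping segments
#'
#' Fixed-length consecutive segments in temporal order; a trailing partial
#' segment is discarded.
#'
#' @param rec a [recording()] (typically band-passed).
#' @param segment_length segment length in seconds (default 5).
#' @return a `segmented_band_data` object: list with `subject_id`, `band`,
#'   `sample_rate`, `segment_length` and `segments` (list of channels x
#'   samples matrices).
#' @export
segment_recording <- function(rec, segment_length = 5) {
  stopifnot(inherits(rec, "recording"))
  ss <- round(segment_length * rec$sample_rate)
  n <- ncol(rec$data)
  if (n < ss) stop("recording shorter than one segment")
  k <- n %/% ss
  segs <- lapply(seq_len(k), function(i) {
    rec$data[, (i - 1L) * ss + seq_len(ss), drop = FALSE]
  })
  structure(
    list(subject_id = rec$subject_id, band = rec$band %||% NA_character_,
         sample_rate = rec$sample_rate, segment_length = segment_length,
         segments = segs),
    class = "segmented_band_data"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
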