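#' Define a frequency band
#'
#' A named frequency interval used for band-pass filtering and per-band
#' network analysis.
#'
#' @param name band label, e.g. `"alpha"`.
#' @param low lower edge in Hz; must satisfy `0 < low < high`.
#' @param high upper edge in Hz.
#' @return a `band_definition` object (list with `name`, `low`, `high`).
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), length(low) == 1L,
            is.numeric(high), length(high) == 1L)
  if (!(low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' The five canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-48 Hz, the
#' standard clinical division of the EEG rhythm spectrum.
#'
#' @return named list of [band_definition()] objects.
#' @examples
#' names(default_bands())
#' @export
default_bands <- function() {
  list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 48)
  )
}

# Resolve a band given either a band_definition or a name from default_bands().
resolve_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) {
    bands <- default_bands()
    if (band %in% names(bands)) return(bands[[band]])
    stop(sprintf("unknown band name '%s'", band))
  }
  stop("band must be a band_definition or the name of a default band")
}
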