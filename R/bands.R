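#' Frequency band definition
#'
#' A band is a half-open frequency interval `[f_lo, f_hi)`. The half-open
#' convention makes the five canonical bands partition 0.5-48 Hz with no bin
#' counted twice by the DFT filters and power integrals.
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param f_lo Lower edge in Hz (inclusive), must be positive.
#' @param f_hi Upper edge in Hz (exclusive), must exceed `f_lo`.
#' @return An object of class `band_def` with fields `name`, `f_lo`, `f_hi`.
#' @examples
#' band_def("alpha", 8, 13)
#' @export
band_def <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop_megconn("band edges must satisfy 0 < f_lo < f_hi", "megconn_invalid_parameter")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_def")
}

#' Canonical resting-state frequency bands
#'
#' The five canonical bands used throughout: delta 0.5-4 Hz, theta 4-8 Hz,
#' alpha 8-13 Hz, beta 13-30 Hz, gamma 30-48 Hz.
#'
#' @return Named list of [band_def()] objects.
#' @export
canonical_bands <- function() {
  list(
    delta = band_def("delta", 0.5, 4),
    theta = band_def("theta", 4, 8),
    alpha = band_def("alpha", 8, 13),
    beta  = band_def("beta", 13, 30),
    gamma = band_def("gamma", 30, 48)
  )
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band_def> %s: [%g, %g) Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

# Accept a band_def or the name of a canonical band.
as_band <- function(band) {
  if (inherits(band, "band_def")) return(band)
  if (is.character(band) && length(band) == 1L) {
    bands <- canonical_bands()
    if (band %in% names(bands)) return(bands[[band]])
  }
  stop_megconn("`band` must be a band_def or a canonical band name", "megconn_invalid_parameter")
}
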