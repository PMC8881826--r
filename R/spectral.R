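# Spectral primitives: discrete-Fourier brick-wall filtering, analytic-signal
# phase/envelope, relative band power, and peak frequency.
#
# All filters share one mask convention: a bin with folded frequency f (the
# magnitude of its signed DFT frequency) is retained iff f_lo <= f < f_hi.
# Masking positive and mirrored negative bins identically keeps the inverse
# transform real, and the half-open interval makes the five canonical bands an
# exact partition of 0.5-48 Hz.

# Folded (two-sided magnitude) frequency of each DFT bin for length n at fs.
folded_freqs <- function(n, fs) {
  k <- 0:(n - 1L)
  pmin(k, n - k) * fs / n
}

fft_mask <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- folded_freqs(n, fs)
  keep <- f >= f_lo & f < f_hi
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Brick-wall DFT band-pass filter
#'
#' Filters a signal by zeroing all DFT bins outside `[f_lo, f_hi)` (positive
#' frequencies and their mirrored negative-frequency counterparts) and
#' inverse-transforming. Output is real and the same length as the input.
#'
#' @param x Numeric vector (one channel), length >= 2.
#' @param band A [band_def()] or canonical band name.
#' @param fs Sampling rate in Hz. `f_hi` must not exceed the Nyquist rate.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' fs <- 256; t <- seq(0, 4 - 1 / fs, by = 1 / fs)
#' x <- cos(2 * pi * 10 * t)
#' y <- fft_bandpass(x, "alpha", fs)  # passband: y ~ x
#' @export
fft_bandpass <- function(x, band, fs) {
  band <- as_band(band)
  if (!is.numeric(x) || length(x) < 2L) {
    stop_megconn("`x` must be a numeric vector of length >= 2", "megconn_invalid_parameter")
  }
  if (band$f_hi > fs / 2) {
    stop_megconn(sprintf("band [%g, %g) exceeds the Nyquist frequency %g Hz",
                         band$f_lo, band$f_hi, fs / 2),
                 "megconn_invalid_parameter")
  }
  fft_mask(x, fs, band$f_lo, band$f_hi)
}

# Analytic signal via the one-sided spectrum (positive frequencies doubled).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope
#'
#' Hilbert (analytic-signal) decomposition of a band-limited signal: the phase
#' is the argument and the envelope the modulus of the analytic signal. Phases
#' and envelopes of band-filtered epochs feed the PLI and AEC-c.
#'
#' @param x Band-limited numeric vector; must not be constant.
#' @return List with numeric vectors `phase` (radians, in (-pi, pi]) and
#'   `envelope` (non-negative), each the same length as `x`.
#' @export
phase_envelope <- function(x) {
  if (stats::sd(x) == 0) {
    stop_megconn("constant (zero-variance) signal has no phase/envelope", "megconn_degenerate")
  }
  z <- analytic_signal(x)
  list(phase = Arg(z), envelope = Mod(z))
}

#' Relative band power
#'
#' Periodogram power summed over each band `[f_lo, f_hi)`, normalized by the
#' total power over the union of the supplied bands (0.5-48 Hz for the
#' canonical set), so the fractions sum to one.
#'
#' @param x Numeric vector (one channel, typically one epoch).
#' @param fs Sampling rate in Hz.
#' @param bands List of [band_def()] objects; defaults to [canonical_bands()].
#' @return Named numeric vector of power fractions, one per band.
#' @export
relative_power <- function(x, fs, bands = canonical_bands()) {
  if (all(x == 0)) {
    stop_megconn("all-zero signal has no power spectrum", "megconn_degenerate")
  }
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  f <- folded_freqs(n, fs)
  band_power <- vapply(bands, function(b) sum(pw[f >= b$f_lo & f < b$f_hi]), numeric(1))
  lo <- min(vapply(bands, function(b) b$f_lo, numeric(1)))
  hi <- max(vapply(bands, function(b) b$f_hi, numeric(1)))
  total <- sum(pw[f >= lo & f < hi])
  if (total == 0) {
    stop_megconn("no power in the analysed 0.5-48 Hz range", "megconn_degenerate")
  }
  stats::setNames(band_power / total, vapply(bands, function(b) b$name, character(1)))
}

#' Peak frequency
#'
#' Frequency of the maximum periodogram power within `range` (default 4-13 Hz,
#' spanning the theta and alpha bands where the dominant resting rhythm lies).
#' Ties are broken toward the lower frequency. A flat spectrum in the range
#' returns the midpoint with a warning.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param range Length-2 numeric search interval in Hz (inclusive).
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(x, fs, range = c(4, 13)) {
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  k <- 0:(n %/% 2)
  f <- k * fs / n
  pw <- pw[seq_along(f)]
  in_range <- f >= range[1] & f <= range[2]
  if (!any(in_range)) {
    stop_megconn("no DFT bin falls inside the peak-frequency range", "megconn_invalid_parameter")
  }
  pr <- pw[in_range]
  fr <- f[in_range]
  # flat: no structure in range, or only numerical dust relative to the
  # spectrum's total power
  if (diff(range(pr)) == 0 || max(pr) <= 1e-12 * max(pw)) {
    warning("flat spectrum in the peak-frequency range; returning the midpoint")
    return(mean(range))
  }
  fr[which.max(pr)]  # which.max returns the first (lowest-frequency) maximum
}

#' Spectral summary of an epoch
#'
#' Relative power in the canonical bands plus peak frequency, averaged over
#' the ROI channels of an epoch.
#'
#' @param epoch An `epoch` object (see [segment_epochs()]).
#' @param bands List of [band_def()]s.
#' @return List with `relative_power` (named vector) and `peak_frequency` (Hz).
#' @export
spectral_summary <- function(epoch, bands = canonical_bands()) {
  stopifnot(inherits(epoch, "epoch"))
  rp <- t(apply(epoch$data, 1L, relative_power, fs = epoch$fs, bands = bands))
  pf <- apply(epoch$data, 1L, peak_frequency, fs = epoch$fs)
  list(relative_power = colMeans(rp), peak_frequency = mean(pf))
}
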