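# Shared fixtures, built in code.

# Sinusoid sampled so that `freq` falls exactly on a DFT bin when
# freq * n / fs is an integer.
sinusoid <- function(freq, fs, n, phase = 0) {
  cos(2 * pi * freq * (0:(n - 1)) / fs - phase)
}

# Epoch wrapper around a channels x samples matrix.
as_epoch <- function(data, fs, quality = 1L, index = 1L) {
  ts <- roi_ts(data, fs)
  e <- segment_epochs(ts, ncol(data))[[1L]]
  e$quality <- quality
  e$index <- index
  e
}

# Config with no oscillations: pure 1/f background sources.
noise_config <- function(n_roi, duration = 14, leakage = 0, noise = 1) {
  sim_config(n_roi = n_roi, duration = duration,
             band_oscillations = data.frame(band = character(0),
                                            freq = numeric(0),
                                            amplitude = numeric(0)),
             noise_amplitude = noise, leakage_strength = leakage)
}

# One pair envelope-coupled in the beta band at weight w.
envelope_config <- function(w, n_roi = 2, duration = 14, noise = 0.5) {
  sim_config(n_roi = n_roi, duration = duration, noise_amplitude = noise,
             band_oscillations = data.frame(band = "beta", freq = 20,
                                            amplitude = 2),
             envelope_coupling = list(list(pairs = rbind(c(1, 2)),
                                           band = "beta", weight = w)))
}

# First epoch of a simulated recording after the standard downsample-by-4.
first_epoch <- function(cfg, seed) {
  segment_epochs(downsample(simulate_roi_signals(cfg, seed = seed), 4L))[[1L]]
}

# Independent oracle: exact two-sided Mann-Whitney p-value by enumerating all
# label assignments of the pooled sample.
mwu_exact_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  m <- n1 * length(b) / 2
  us <- apply(idx, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - m) >= abs(u_obs - m) - 1e-12)
}

# Independent oracle: Benjamini-Hochberg step-up by its definition.
bh_stepup_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}
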