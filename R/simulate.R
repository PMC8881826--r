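# Synthetic cohort generator. Every downstream stage is exercised on 90-ROI
# (or smaller) signals whose ground truth is fully controlled:
#   * 1/f-shaped background noise (spectrally shaped white noise),
#   * band-limited oscillations (narrowband Gaussian carriers),
#   * phase coupling: a shared narrowband driver, phase-shifted by a constant
#     lag in the analytic domain and mixed s * driver + (1 - s) * private,
#   * envelope coupling: independent carriers multiplied by a convex mixture
#     of a shared and a private slow (< 1 Hz) positive modulator,
#   * leakage: instantaneous row-stochastic mixing applied last.

default_oscillations <- function() {
  data.frame(band = c("theta", "alpha", "beta"),
             freq = c(6, 10, 20),
             amplitude = c(0.4, 1.0, 0.5),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Declares the generative model for one group's ROI time series. Defaults
#' emulate eyes-closed resting-state source signals: a dominant 10 Hz alpha
#' rhythm with weaker theta and beta oscillations over 1/f background noise.
#'
#' @param n_roi Number of ROIs (default 90).
#' @param fs_raw Acquisition sampling rate in Hz (default 1250).
#' @param duration Recording length in seconds (default 160, enough for 12
#'   epochs of 4096 samples after downsampling by 4).
#' @param band_oscillations data.frame with columns `band`, `freq` (Hz),
#'   `amplitude` (RMS relative to unit-RMS noise).
#' @param one_over_f_exponent Spectral exponent of the background (power
#'   proportional to `f^-exponent`, default 1).
#' @param noise_amplitude RMS of the 1/f background (0 disables noise).
#' @param phase_coupling List of couplings, each a list with `pairs` (2-column
#'   matrix of ROI indices), `band` (name matching an oscillation), `lag`
#'   (radians, not congruent to 0 mod pi if a non-zero PLI is intended), and
#'   `strength` in \[0, 1\].
#' @param envelope_coupling List of couplings, each a list with `pairs`,
#'   `band`, and `weight` in \[0, 1\] (shared-modulator share).
#' @param leakage_strength Off-diagonal mixing share in \[0, 1).
#' @param group_effects Named list of parameter deltas for an affected group;
#'   see [apply_group_effects()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_roi = 90L, fs_raw = 1250, duration = 160,
                       band_oscillations = default_oscillations(),
                       one_over_f_exponent = 1, noise_amplitude = 1,
                       phase_coupling = list(), envelope_coupling = list(),
                       leakage_strength = 0, group_effects = list()) {
  stopifnot(is_count(n_roi), fs_raw > 0, duration > 0,
            is.data.frame(band_oscillations),
            all(c("band", "freq", "amplitude") %in% names(band_oscillations)))
  if (leakage_strength < 0 || leakage_strength >= 1) {
    stop_megconn("`leakage_strength` must lie in [0, 1)", "megconn_invalid_parameter")
  }
  check_coupling <- function(cp, field) {
    for (c0 in cp) {
      stopifnot(is.list(c0), !is.null(c0$pairs), !is.null(c0$band))
      val <- c0[[field]]
      if (is.null(val) || val < 0 || val > 1) {
        stop_megconn(sprintf("coupling `%s` must lie in [0, 1]", field),
                     "megconn_invalid_parameter")
      }
      pr <- matrix(as.integer(c0$pairs), ncol = 2L)
      if (any(pr < 1L) || any(pr > n_roi) || any(pr[, 1] == pr[, 2])) {
        stop_megconn("coupling pairs must index distinct ROIs", "megconn_invalid_parameter")
      }
      if (!c0$band %in% band_oscillations$band) {
        stop_megconn("coupling band has no matching oscillation", "megconn_invalid_parameter")
      }
    }
  }
  check_coupling(phase_coupling, "strength")
  check_coupling(envelope_coupling, "weight")
  structure(list(n_roi = as.integer(n_roi), fs_raw = fs_raw, duration = duration,
                 band_oscillations = band_oscillations,
                 one_over_f_exponent = one_over_f_exponent,
                 noise_amplitude = noise_amplitude,
                 phase_coupling = phase_coupling,
                 envelope_coupling = envelope_coupling,
                 leakage_strength = leakage_strength,
                 group_effects = group_effects),
            class = "sim_config")
}

#' Apply group-effect deltas to a configuration
#'
#' Produces the affected ("AD-like") group's configuration from a base
#' configuration and named deltas: `phase_strength` and `envelope_weight`
#' (named by band or a single unnamed scalar added to every coupling of that
#' kind, clamped to \[0, 1\]) and `osc_amplitude` (named by band, added to the
#' oscillation amplitudes, floored at 0).
#'
#' @param config A [sim_config()].
#' @param effects Named list of deltas; defaults to `config$group_effects`.
#' @return Modified `sim_config`.
#' @export
apply_group_effects <- function(config, effects = config$group_effects) {
  stopifnot(inherits(config, "sim_config"))
  clamp01 <- function(x) pmin(1, pmax(0, x))
  delta_for <- function(delta, band) {
    if (is.null(names(delta))) delta[[1L]]
    else if (band %in% names(delta)) delta[[band]]
    else 0
  }
  if (!is.null(effects$phase_strength)) {
    config$phase_coupling <- lapply(config$phase_coupling, function(c0) {
      c0$strength <- clamp01(c0$strength + delta_for(effects$phase_strength, c0$band))
      c0
    })
  }
  if (!is.null(effects$envelope_weight)) {
    config$envelope_coupling <- lapply(config$envelope_coupling, function(c0) {
      c0$weight <- clamp01(c0$weight + delta_for(effects$envelope_weight, c0$band))
      c0
    })
  }
  if (!is.null(effects$osc_amplitude)) {
    bo <- config$band_oscillations
    for (b in names(effects$osc_amplitude)) {
      bo$amplitude[bo$band == b] <- pmax(0, bo$amplitude[bo$band == b] +
                                           effects$osc_amplitude[[b]])
    }
    config$band_oscillations <- bo
  }
  config$group_effects <- list()
  config
}

#' Zero-lag leakage mixing matrix
#'
#' Row-stochastic instantaneous mixing matrix emulating volume conduction /
#' field spread: each row keeps `1 - leakage_strength` of its own source and
#' spreads the remaining mass over the other ROIs with random (distance-free)
#' non-negative weights. Rows sum to one; `leakage_strength = 0` gives the
#' identity.
#'
#' @param n_roi Number of ROIs.
#' @param leakage_strength Off-diagonal share in \[0, 1).
#' @param seed Integer seed (the matrix is deterministic given the seed).
#' @return `n_roi x n_roi` numeric matrix.
#' @export
build_leakage_matrix <- function(n_roi, leakage_strength, seed = NULL) {
  stopifnot(is_count(n_roi))
  if (!is.numeric(leakage_strength) || leakage_strength < 0 || leakage_strength >= 1) {
    stop_megconn("`leakage_strength` must lie in [0, 1)", "megconn_invalid_parameter")
  }
  if (leakage_strength == 0) return(diag(n_roi))
  local_seed(seed, {
    L <- matrix(0, n_roi, n_roi)
    for (i in seq_len(n_roi)) {
      w <- stats::runif(n_roi - 1L)
      L[i, -i] <- leakage_strength * w / sum(w)
      L[i, i] <- 1 - leakage_strength
    }
    L
  })
}

# 1/f^exponent-shaped Gaussian noise of length n, unit RMS before scaling.
one_over_f_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  X <- stats::fft(w)
  f <- folded_freqs(n, fs)
  shape <- c(0, f[-1]^(-exponent / 2))  # kill DC, amplitude ~ f^(-a/2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Complex narrowband analytic carrier at center frequency f_c, unit-RMS real
# part. Built by band-limiting white noise to [f_c - bw/2, f_c + bw/2] and
# taking the analytic signal, so Re(z * exp(-1i * lag)) is an exactly
# constant-lag copy.
narrowband_carrier <- function(n, fs, f_c, bw = 2) {
  lo <- max(f_c - bw / 2, 0.1)
  hi <- min(f_c + bw / 2, fs / 2)
  x <- fft_mask(stats::rnorm(n), fs, lo, hi)
  z <- analytic_signal(x)
  z / stats::sd(Re(z))
}

# Standardized slow (< f_max Hz) modulator fluctuation.
slow_fluctuation <- function(n, fs, f_max = 1) {
  m <- fft_mask(stats::rnorm(n), fs, 0.01, f_max)
  m / stats::sd(m)
}

# Strictly positive unit-mean modulator from a standardized fluctuation.
as_modulator <- function(z, depth = 0.5) pmax(1 + depth * z, 0.05)

#' Simulate one subject's ROI time series
#'
#' Generates `n_roi` channels at the raw sampling rate following the
#' configuration: per-ROI 1/f background plus band-limited oscillations, with
#' the configured phase couplings (shared constant-lag driver), envelope
#' couplings (shared slow modulator), and zero-lag leakage mixing applied
#' last. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [roi_ts()] at `config$fs_raw` Hz.
#' @export
simulate_roi_signals <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_raw
  n <- floor(config$duration * fs)
  if (n < 16L) {
    stop_megconn("duration too short", "megconn_invalid_parameter")
  }
  n_roi <- config$n_roi
  local_seed(seed, {
    x <- matrix(0, n_roi, n)
    if (config$noise_amplitude > 0) {
      for (i in seq_len(n_roi)) {
        x[i, ] <- config$noise_amplitude *
          one_over_f_noise(n, fs, config$one_over_f_exponent)
      }
    }
    bo <- config$band_oscillations
    for (k in seq_len(nrow(bo))) {
      band_name <- bo$band[k]
      f_c <- bo$freq[k]
      amp <- bo$amplitude[k]
      if (amp <= 0) next
      # Component construction per ROI for this band.
      comp <- matrix(0, n_roi, n)
      private <- lapply(seq_len(n_roi), function(i) narrowband_carrier(n, fs, f_c))
      for (i in seq_len(n_roi)) comp[i, ] <- Re(private[[i]])
      for (c0 in config$phase_coupling) {
        if (c0$band != band_name) next
        pr <- matrix(as.integer(c0$pairs), ncol = 2L)
        s <- c0$strength
        for (p in seq_len(nrow(pr))) {
          i <- pr[p, 1L]; j <- pr[p, 2L]
          driver <- narrowband_carrier(n, fs, f_c)
          comp[i, ] <- s * Re(driver) + (1 - s) * Re(private[[i]])
          comp[j, ] <- s * Re(driver * exp(-1i * c0$lag)) + (1 - s) * Re(private[[j]])
        }
      }
      for (c0 in config$envelope_coupling) {
        if (c0$band != band_name) next
        pr <- matrix(as.integer(c0$pairs), ncol = 2L)
        w <- c0$weight
        for (p in seq_len(nrow(pr))) {
          i <- pr[p, 1L]; j <- pr[p, 2L]
          # sqrt weights: the shared share of the modulator *variance* is w,
          # so the modulator correlation of the pair equals the weight.
          zs <- slow_fluctuation(n, fs)
          zi <- sqrt(w) * zs + sqrt(1 - w) * slow_fluctuation(n, fs)
          zj <- sqrt(w) * zs + sqrt(1 - w) * slow_fluctuation(n, fs)
          comp[i, ] <- as_modulator(zi) * Re(private[[i]])
          comp[j, ] <- as_modulator(zj) * Re(private[[j]])
        }
      }
      x <- x + amp * comp
    }
    if (config$leakage_strength > 0) {
      L <- build_leakage_matrix(n_roi, config$leakage_strength,
                                seed = derive_seed(seed %||% 0L, 777L))
      x <- L %*% x
    }
    roi_ts(x, fs, if (n_roi == 90L) aal90_labels() else NULL)
  })
}

subject_record <- function(subject_id, group, age, mmse, epochs) {
  structure(list(subject_id = subject_id, group = group, age = age,
                 mmse = mmse, epochs = epochs),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), age %.1f, MMSE %s, %d epochs\n",
              x$subject_id, x$group, x$age,
              ifelse(is.na(x$mmse), "NA", x$mmse), length(x$epochs)))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat(sprintf("<cohort> '%s': %d subjects (%s)\n", x$name, length(x$subjects),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

simulate_subject <- function(config, subject_id, group, seed,
                             downsample_factor = 4L, epoch_samples = 4096L) {
  ts_raw <- simulate_roi_signals(config, seed = seed)
  ts <- downsample(ts_raw, downsample_factor)
  epochs <- segment_epochs(ts, epoch_samples)
  if (length(epochs) == 0L) {
    stop_megconn("duration too short to hold one epoch after downsampling",
                 "megconn_invalid_parameter")
  }
  local_seed(derive_seed(seed, 101L), {
    quality <- sample(1:4, length(epochs), replace = TRUE)
    for (i in seq_along(epochs)) epochs[[i]]$quality <- quality[i]
    age <- if (group == "AD") {
      min(90, max(40, stats::rnorm(1, 65, 7)))
    } else {
      min(90, max(40, stats::rnorm(1, 56.5, 9)))
    }
    mmse <- if (group == "AD") sample(12:29, 1L) else sample(24:30, 1L)
    subject_record(subject_id, group, age, mmse, epochs)
  })
}

#' Simulate a two-group cohort
#'
#' Generates `n_scd` SCD-like and `n_ad` AD-like subjects. Each subject's
#' signals are drawn with a seed derived deterministically from the master
#' seed; ages come from group-specific truncated normals (SCD ~ N(56.5, 9),
#' AD ~ N(65, 7), truncated to 40-90 years) and MMSE from group-specific
#' uniform integer ranges (SCD 24-30, AD 12-29). Epoch quality scores are
#' uniform on \{1, 2, 3, 4\}, independent of group.
#'
#' @param config_scd,config_ad [sim_config()]s for the two groups. Passing the
#'   same config simulates the global null.
#' @param n_scd,n_ad Group sizes (>= 2).
#' @param seed Integer master seed.
#' @param name Cohort name.
#' @param downsample_factor Decimation factor applied before segmentation.
#' @param epoch_samples Samples per epoch.
#' @return A `cohort` object (list of `subject_record`s).
#' @export
simulate_cohort <- function(config_scd, config_ad, n_scd, n_ad, seed = NULL,
                            name = "simulated", downsample_factor = 4L,
                            epoch_samples = 4096L) {
  stopifnot(inherits(config_scd, "sim_config"), inherits(config_ad, "sim_config"))
  if (!is_count(n_scd) || !is_count(n_ad) || n_scd < 2 || n_ad < 2) {
    stop_megconn("need at least two subjects per group", "megconn_invalid_parameter")
  }
  seed <- seed %||% 1L
  subjects <- vector("list", n_scd + n_ad)
  k <- 0L
  for (i in seq_len(n_scd)) {
    k <- k + 1L
    subjects[[k]] <- simulate_subject(config_scd, sprintf("SCD%03d", i), "SCD",
                                      derive_seed(seed, k),
                                      downsample_factor, epoch_samples)
  }
  for (i in seq_len(n_ad)) {
    k <- k + 1L
    subjects[[k]] <- simulate_subject(config_ad, sprintf("AD%03d", i), "AD",
                                      derive_seed(seed, k),
                                      downsample_factor, epoch_samples)
  }
  structure(list(subjects = subjects, name = name), class = "cohort")
}
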