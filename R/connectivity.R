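# Functional connectivity metrics.
#
# PLI: the phase lag index |< sign[sin(dphi(t_k))] >|, the absolute mean over
# time of the sign of the sine of the instantaneous phase difference. It
# measures the asymmetry of the phase-difference distribution around zero, so
# any purely zero-lag (volume-conducted) dependency contributes nothing.
#
# AEC-c: the amplitude envelope correlation after pairwise orthogonalization.
# Before correlating Hilbert envelopes, the zero-lag component of one
# band-filtered signal is regressed out of the other (both directions, raw
# Pearson r averaged), then rescaled (r + 1) / 2 into [0, 1], so that 0.5 is
# the null value for independent envelopes.

#' Phase lag index of one pair
#'
#' `|mean(sign(sin(phase_x - phase_y)))|`, with `sign(0) = 0`. Equals 1 for a
#' constant non-zero phase lag strictly inside (0, pi) and 0 for zero-lag
#' (identical-phase) signals.
#'
#' @param phase_x,phase_y Instantaneous phase vectors in radians (equal
#'   length, >= 2), e.g. from [phase_envelope()].
#' @return PLI value in \[0, 1\].
#' @export
pli_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y) || length(phase_x) < 2L) {
    stop_megconn("phase vectors must have equal length >= 2", "megconn_invalid_input")
  }
  abs(mean(sign(sin(phase_x - phase_y))))
}

#' Regress one signal out of another
#'
#' Ordinary least squares of `y` on `x` with an intercept over the epoch; the
#' residual is exactly uncorrelated with `x`, which removes any instantaneous
#' (zero-lag) linear leakage of `x` into `y`.
#'
#' @param x,y Numeric vectors of equal length; `x` must not be constant.
#' @return Residual vector of the regression of `y` on `x`.
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop_megconn("signals must have equal length", "megconn_invalid_input")
  }
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    stop_megconn("regressor signal is constant", "megconn_degenerate")
  }
  b <- stats::cov(x, y) / vx
  y - (mean(y) - b * mean(x)) - b * x
}

#' Amplitude envelope correlation (rescaled)
#'
#' Pearson correlation between two amplitude envelopes, rescaled to
#' `(r + 1) / 2` so values lie in \[0, 1\] with 0.5 the null. Without
#' orthogonalization this metric is inflated by zero-lag leakage; it is kept
#' as the leakage-sensitive comparator for the corrected AEC-c.
#'
#' @param env_x,env_y Non-constant envelope vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
aec_pair <- function(env_x, env_y) {
  if (length(env_x) != length(env_y)) {
    stop_megconn("envelopes must have equal length", "megconn_invalid_input")
  }
  if (stats::sd(env_x) == 0 || stats::sd(env_y) == 0) {
    stop_megconn("constant envelope", "megconn_degenerate")
  }
  (stats::cor(env_x, env_y) + 1) / 2
}

#' Corrected amplitude envelope correlation of one pair
#'
#' Pairwise-orthogonalized AEC: regress `y` on `x` and correlate the envelope
#' of `x` with the envelope of the residual; repeat with the roles swapped;
#' average the two raw correlations and rescale `(r + 1) / 2`.
#'
#' Orthogonalization acts on the band-filtered time series (envelopes are
#' taken afterwards), which removes the zero-lag leakage component exactly.
#' Set `on = "envelope"` to regress on the Hilbert envelopes instead.
#'
#' @param x_band,y_band Band-filtered signals of equal length, non-constant.
#' @param on Orthogonalization target: `"signal"` (default) or `"envelope"`.
#' @return AEC-c value in \[0, 1\].
#' @export
aec_c_pair <- function(x_band, y_band, on = c("signal", "envelope")) {
  on <- match.arg(on)
  if (length(x_band) != length(y_band)) {
    stop_megconn("signals must have equal length", "megconn_invalid_input")
  }
  if (stats::sd(x_band) == 0 || stats::sd(y_band) == 0) {
    stop_megconn("constant signal", "megconn_degenerate")
  }
  # remove any DC pedestal: the envelope belongs to the oscillatory part, and
  # demeaning makes the metric exactly invariant to positive affine scaling
  x_band <- x_band - mean(x_band)
  y_band <- y_band - mean(y_band)
  env <- function(s) Mod(analytic_signal(s))
  one_direction <- if (on == "signal") {
    function(a, b) {   # leakage of a removed from b; envelopes compared
      res <- orthogonalize_pair(a, b)
      if (stats::sd(res) < 1e-10 * stats::sd(b)) {
        stop_megconn("signals are collinear: orthogonalized residual vanishes",
                     "megconn_degenerate")
      }
      e <- env(res)
      if (stats::sd(e) == 0) stop_megconn("degenerate residual envelope", "megconn_degenerate")
      stats::cor(env(a), e)
    }
  } else {
    function(a, b) {
      ea <- env(a); eb <- env(b)
      res <- orthogonalize_pair(ea, eb)
      if (stats::sd(res) < 1e-10 * stats::sd(eb)) {
        stop_megconn("envelopes are collinear: orthogonalized residual vanishes",
                     "megconn_degenerate")
      }
      stats::cor(ea, res)
    }
  }
  r <- (one_direction(x_band, y_band) + one_direction(y_band, x_band)) / 2
  (r + 1) / 2
}

metric_null_value <- function(metric) {
  switch(metric, pli = 0, aec = 0.5, aec_c = 0.5)
}

#' Connectivity matrix of one epoch
#'
#' Band-pass filters every ROI channel of the epoch and computes the chosen
#' metric for all unordered ROI pairs, mirrored into a symmetric matrix with
#' a zero diagonal. Degenerate pairs (e.g. exactly collinear channels) are set
#' to the metric's null value (PLI 0, AEC/AEC-c 0.5) and counted in the
#' `n_degenerate` attribute.
#'
#' @param epoch An `epoch` object.
#' @param band A [band_def()] or canonical band name.
#' @param metric One of `"pli"`, `"aec"`, `"aec_c"`.
#' @param on Orthogonalization target for AEC-c, see [aec_c_pair()].
#' @return A `conn_matrix`: symmetric numeric matrix with `metric`, `band`,
#'   and `n_degenerate` attributes and ROI labels as dimnames.
#' @export
connectivity_matrix <- function(epoch, band, metric = c("pli", "aec", "aec_c"),
                                on = "signal") {
  stopifnot(inherits(epoch, "epoch"))
  metric <- match.arg(metric)
  band <- as_band(band)
  n_roi <- nrow(epoch$data)
  filt <- t(apply(epoch$data, 1L, fft_bandpass, band = band, fs = epoch$fs))
  m <- matrix(0, n_roi, n_roi)
  n_degenerate <- 0L
  if (metric == "pli") {
    phases <- t(apply(filt, 1L, function(s) Arg(analytic_signal(s))))
    for (i in seq_len(n_roi - 1L)) {
      for (j in (i + 1L):n_roi) {
        v <- tryCatch(pli_pair(phases[i, ], phases[j, ]),
                      megconn_degenerate = function(e) NA_real_)
        if (is.na(v)) { v <- metric_null_value(metric); n_degenerate <- n_degenerate + 1L }
        m[i, j] <- m[j, i] <- v
      }
    }
  } else if (metric == "aec") {
    envs <- t(apply(filt, 1L, function(s) Mod(analytic_signal(s))))
    for (i in seq_len(n_roi - 1L)) {
      for (j in (i + 1L):n_roi) {
        v <- tryCatch(aec_pair(envs[i, ], envs[j, ]),
                      megconn_degenerate = function(e) NA_real_)
        if (is.na(v)) { v <- metric_null_value(metric); n_degenerate <- n_degenerate + 1L }
        m[i, j] <- m[j, i] <- v
      }
    }
  } else {
    for (i in seq_len(n_roi - 1L)) {
      for (j in (i + 1L):n_roi) {
        v <- tryCatch(aec_c_pair(filt[i, ], filt[j, ], on = on),
                      megconn_degenerate = function(e) NA_real_)
        if (is.na(v)) { v <- metric_null_value(metric); n_degenerate <- n_degenerate + 1L }
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  labels <- epoch$labels %||% paste0("ROI_", seq_len(n_roi))
  dimnames(m) <- list(labels, labels)
  structure(m, metric = metric, band = band$name, n_degenerate = n_degenerate,
            class = c("conn_matrix", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-ROI connectivity strength
#'
#' Mean of each ROI's 89 off-diagonal connections (row mean excluding the
#' diagonal). The mean of the strengths is the global FC.
#'
#' @param m A `conn_matrix` (or plain symmetric matrix with zero diagonal).
#' @return Named numeric vector of ROI strengths.
#' @export
roi_strength <- function(m) {
  n <- nrow(m)
  stats::setNames(rowSums(m) / (n - 1L), rownames(m))
}

#' Global functional connectivity
#'
#' Mean of the per-ROI strengths (equivalently the mean off-diagonal entry).
#'
#' @param m A `conn_matrix`.
#' @return Scalar global FC.
#' @export
global_fc <- function(m) mean(roi_strength(m))

#' Subject-level connectivity
#'
#' Selects the subject's best `n_epochs` epochs, computes the connectivity
#' matrix for each, and averages element-wise across epochs.
#'
#' @param subject A `subject_record` (see [simulate_cohort()]).
#' @param band A [band_def()] or canonical band name.
#' @param metric `"pli"`, `"aec"`, or `"aec_c"`.
#' @param n_epochs Number of epochs to average (default 10).
#' @param on Orthogonalization target for AEC-c.
#' @return List with `matrix` (epoch-mean `conn_matrix`), `strength`
#'   (ROI-strength vector), and `global_fc` (scalar).
#' @export
subject_connectivity <- function(subject, band, metric = "pli", n_epochs = 10L,
                                 on = "signal") {
  stopifnot(inherits(subject, "subject_record"))
  sel <- select_best_epochs(subject$epochs, k = n_epochs)
  mats <- lapply(sel, connectivity_matrix, band = band, metric = metric, on = on)
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  attributes(avg) <- attributes(mats[[1L]])
  list(matrix = avg, strength = roi_strength(avg), global_fc = global_fc(avg))
}

#' Cohort table of global FC values
#'
#' One row per subject x metric x band with the subject's epoch-averaged
#' global FC, plus demographics, ready for the group-level models. When
#' `with_power = TRUE` a `rel_power` column holds the subject's mean relative
#' power in the row's band (the covariate model of the pipeline).
#'
#' @param cohort A `cohort`.
#' @param metrics Character vector of metrics.
#' @param bands List of bands (defaults to the canonical five).
#' @param n_epochs Epochs averaged per subject.
#' @param with_power Attach per-band relative power as `rel_power`.
#' @param on Orthogonalization target for AEC-c.
#' @return data.frame with columns subject_id, group, age, mmse, metric, band,
#'   global_fc (and rel_power).
#' @export
cohort_fc_table <- function(cohort, metrics = c("pli", "aec_c"),
                            bands = canonical_bands(), n_epochs = 10L,
                            with_power = FALSE, on = "signal") {
  stopifnot(inherits(cohort, "cohort"))
  band_names <- vapply(bands, function(b) as_band(b)$name, character(1))
  rows <- list()
  for (subj in cohort$subjects) {
    rp <- NULL
    if (with_power) {
      sel <- select_best_epochs(subj$epochs, k = n_epochs)
      rp_mat <- vapply(sel, function(e) spectral_summary(e, bands)$relative_power,
                       numeric(length(bands)))
      rp <- rowMeans(matrix(rp_mat, nrow = length(bands)))
      names(rp) <- band_names
    }
    for (metric in metrics) {
      for (b in bands) {
        b <- as_band(b)
        res <- subject_connectivity(subj, b, metric, n_epochs = n_epochs, on = on)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$subject_id, group = subj$group, age = subj$age,
          mmse = subj$mmse, metric = metric, band = b$name,
          global_fc = res$global_fc,
          rel_power = if (with_power) rp[[b$name]] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!with_power) out$rel_power <- NULL
  out
}

#' Per-ROI strength matrix for a cohort
#'
#' Subjects x ROI matrix of epoch-averaged connectivity strengths for one
#' metric and band, the input to the regional Mann-Whitney comparisons.
#'
#' @inheritParams cohort_fc_table
#' @param metric Single metric name.
#' @param band Single band.
#' @return List with `strengths` (n_subjects x n_roi matrix, subject ids as
#'   rownames) and `group` (character vector).
#' @export
cohort_strengths <- function(cohort, metric, band, n_epochs = 10L, on = "signal") {
  stopifnot(inherits(cohort, "cohort"))
  band <- as_band(band)
  res <- lapply(cohort$subjects, function(s)
    subject_connectivity(s, band, metric, n_epochs = n_epochs, on = on)$strength)
  strengths <- do.call(rbind, res)
  rownames(strengths) <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  list(strengths = strengths,
       group = vapply(cohort$subjects, function(s) s$group, character(1)))
}
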