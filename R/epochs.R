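# Epoch machinery: anti-aliased downsampling, fixed-length segmentation, and
# quality-based epoch selection. The analysis pipeline mirrors the acquisition
# bookkeeping: 1250 Hz recordings downsampled by 4 to 312.5 Hz, cut into
# 4096-sample (13.1072 s) epochs, 10 best-quality epochs retained per subject.

new_epoch <- function(data, fs, quality = NA_integer_, index = NA_integer_,
                      labels = NULL) {
  structure(list(data = data, fs = fs, quality = quality, index = index,
                 labels = labels),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch #%s> %d ROIs x %d samples @ %g Hz, quality %s\n",
              x$index, nrow(x$data), ncol(x$data), x$fs, x$quality))
  invisible(x)
}

#' Downsample an ROI time series
#'
#' Applies an anti-alias low-pass (brick-wall DFT mask at 0.8 x the new
#' Nyquist frequency) and keeps every `factor`-th sample. The new sampling
#' rate is `fs / factor` and need not be an integer (1250 / 4 = 312.5 Hz).
#'
#' @param ts A [roi_ts()].
#' @param factor Positive integer decimation factor. `factor = 1` returns the
#'   input unchanged.
#' @return A [roi_ts()] with `floor(n / factor)` samples at `fs / factor` Hz.
#' @export
downsample <- function(ts, factor) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!is_count(factor)) {
    stop_megconn("`factor` must be a positive integer", "megconn_invalid_parameter")
  }
  n <- ncol(ts$data)
  if (factor > n) {
    stop_megconn("`factor` exceeds the signal length", "megconn_invalid_parameter")
  }
  if (factor == 1) return(ts)
  new_fs <- ts$fs / factor
  cutoff <- 0.8 * new_fs / 2
  filtered <- t(apply(ts$data, 1L, fft_mask, fs = ts$fs, f_lo = 0, f_hi = cutoff))
  idx <- seq.int(1L, by = factor, length.out = n %/% factor)
  roi_ts(filtered[, idx, drop = FALSE], new_fs, ts$labels)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the maximal set of consecutive, non-overlapping `n_samples`-sample
#' windows from the start of the recording; any trailing remainder is
#' discarded. Epoch quality is unset (`NA`) until assigned.
#'
#' @param ts A [roi_ts()].
#' @param n_samples Samples per epoch (default 4096).
#' @return List of `epoch` objects (empty, with a warning, if the recording is
#'   shorter than one epoch).
#' @export
segment_epochs <- function(ts, n_samples = 4096L) {
  stopifnot(inherits(ts, "roi_ts"), is_count(n_samples))
  n <- ncol(ts$data)
  n_ep <- n %/% n_samples
  if (n_ep == 0L) {
    warning("recording shorter than one epoch; returning an empty list")
    return(list())
  }
  lapply(seq_len(n_ep), function(i) {
    cols <- ((i - 1L) * n_samples + 1L):(i * n_samples)
    new_epoch(ts$data[, cols, drop = FALSE], ts$fs, index = i, labels = ts$labels)
  })
}

#' Select the best-quality epochs
#'
#' Keeps the `k` epochs with the best (numerically lowest) quality score:
#' 1 = artefact-free down to 4 = strong artefacts. Ties are broken by earlier
#' position in the recording; the selection is returned in recording order.
#'
#' @param epochs List of `epoch` objects with integer quality scores 1-4.
#' @param k Number of epochs to keep (default 10).
#' @return List of `k` epochs in recording order.
#' @export
select_best_epochs <- function(epochs, k = 10L) {
  stopifnot(is.list(epochs), is_count(k))
  if (length(epochs) < k) {
    stop_megconn(sprintf("subject has %d epochs but %d are required", length(epochs), k),
                 "megconn_insufficient_data")
  }
  quality <- vapply(epochs, function(e) as.integer(e$quality), integer(1))
  index <- vapply(epochs, function(e) as.integer(e$index), integer(1))
  if (anyNA(quality) || !all(quality %in% 1:4)) {
    stop_megconn("all epochs must carry an integer quality score in 1-4", "megconn_invalid_parameter")
  }
  picked <- order(quality, index)[seq_len(k)]
  epochs[picked[order(index[picked])]]
}
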