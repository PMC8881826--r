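#' Multichannel ROI time series
#'
#' Container for source-space region-of-interest (ROI) time series: a real
#' matrix with one row per ROI, the sampling rate, and ordered ROI labels.
#'
#' @param data Numeric matrix, `n_roi x n_samples`, finite values.
#' @param fs Sampling rate in Hz, positive scalar.
#' @param labels Character vector of ROI names, one per row. Defaults to
#'   `ROI_1 ... ROI_n`.
#' @return An object of class `roi_ts` with fields `data`, `fs`, `labels`.
#' @export
roi_ts <- function(data, fs, labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_megconn("`data` must be a numeric matrix (ROIs x samples)", "megconn_invalid_parameter")
  }
  if (!all(is.finite(data))) {
    stop_megconn("`data` contains non-finite values", "megconn_invalid_parameter")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_megconn("`fs` must be a positive scalar (Hz)", "megconn_invalid_parameter")
  }
  if (is.null(labels)) labels <- paste0("ROI_", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop_megconn("length(labels) must equal nrow(data)", "megconn_invalid_parameter")
  }
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' AAL-90 region labels
#'
#' Ordered labels for the 90-region automated-anatomical-labelling (AAL)
#' parcellation used for the connectivity matrices: 78 cortical plus 12 deep
#' grey-matter regions. The ordering follows the standard matrix block layout:
#' rows 1-15 left frontal, 16-21 left parietal, 22-27 left occipital, 28-39
#' left temporal, 40-54 right frontal, 55-60 right parietal, 61-66 right
#' occipital, 67-78 right temporal, and 79-90 subcortical.
#'
#' @param full Return the full table (label, lobe, hemisphere) instead of the
#'   label vector.
#' @return Character vector of 90 labels, or a data frame when `full = TRUE`.
#' @export
aal90_labels <- function(full = FALSE) {
  path <- system.file("extdata", "aal90_labels.tsv", package = "megconn",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (full) tab else tab$label
}
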