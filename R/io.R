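# File formats. The canonical time-series interchange is delimited text with a
# two-line header (sampling rate, then ROI labels), one tab-separated row of
# samples per ROI. Cohort membership travels in a tab-separated manifest:
# subject_id, group, age, mmse, timeseries_path, quality_scores
# (comma-separated integers, one per epoch in recording order).

#' Write an ROI time series to a delimited text file
#'
#' Format: line 1 `#fs<TAB><rate>`, line 2 `#roi<TAB><label>...`, then one
#' tab-separated numeric row per ROI at full double precision.
#'
#' @param ts A [roi_ts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#fs\t%.17g", ts$fs), con)
  writeLines(paste(c("#roi", ts$labels), collapse = "\t"), con)
  utils::write.table(format(ts$data, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ROI time series
#'
#' Parses the format written by [write_timeseries()]; malformed headers,
#' non-numeric cells, and label/row mismatches raise errors naming the
#' offending line.
#'
#' @param path File path.
#' @return A [roi_ts()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    stop_megconn(sprintf("file not found: %s", path), "megconn_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#fs") ||
      !startsWith(lines[2L], "#roi")) {
    stop_megconn(sprintf("%s: lines 1-2 must be '#fs' and '#roi' headers", path),
                 "megconn_parse_error")
  }
  fs <- suppressWarnings(as.numeric(strsplit(lines[1L], "\t")[[1L]][2L]))
  if (!is.finite(fs) || fs <= 0) {
    stop_megconn(sprintf("%s: line 1: invalid sampling rate", path), "megconn_parse_error")
  }
  labels <- strsplit(lines[2L], "\t")[[1L]][-1L]
  body <- lines[-(1:2)]
  if (length(body) != length(labels)) {
    stop_megconn(sprintf("%s: header names %d ROIs but file has %d data rows",
                         path, length(labels), length(body)),
                 "megconn_parse_error")
  }
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t")[[1L]]))
    if (anyNA(v)) {
      stop_megconn(sprintf("%s: line %d: non-numeric cell", path, i + 2L),
                   "megconn_parse_error")
    }
    v
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop_megconn(sprintf("%s: rows have unequal sample counts", path), "megconn_parse_error")
  }
  roi_ts(do.call(rbind, rows), fs, labels)
}

#' Read a cohort manifest
#'
#' Tab-separated file with columns subject_id, group, age, mmse,
#' timeseries_path, quality_scores. Missing MMSE (`NA`) is tolerated;
#' duplicate subject ids, unknown group labels, and quality scores outside
#' 1-4 are validation errors.
#'
#' @param path Manifest path.
#' @param check_paths Require the referenced time-series files to exist
#'   (relative paths are resolved against the manifest's directory).
#' @return data.frame with `quality_scores` as a list column of integer
#'   vectors.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop_megconn(sprintf("file not found: %s", path), "megconn_io_error")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "age", "mmse", "timeseries_path", "quality_scores")
  if (!all(needed %in% names(d))) {
    stop_megconn(sprintf("manifest must have columns: %s", paste(needed, collapse = ", ")),
                 "megconn_parse_error")
  }
  if (anyDuplicated(d$subject_id)) {
    stop_megconn("duplicate subject_id in manifest", "megconn_validation_error")
  }
  bad <- setdiff(unique(d$group), c("AD", "SCD"))
  if (length(bad)) {
    stop_megconn(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
                 "megconn_validation_error")
  }
  if (any(!is.na(d$mmse) & (d$mmse < 0 | d$mmse > 30))) {
    stop_megconn("mmse outside 0-30", "megconn_validation_error")
  }
  qs <- lapply(strsplit(as.character(d$quality_scores), ","), function(v) {
    iv <- suppressWarnings(as.integer(v))
    if (anyNA(iv) || !all(iv %in% 1:4)) {
      stop_megconn("quality scores must be integers 1-4", "megconn_validation_error")
    }
    iv
  })
  d$quality_scores <- I(qs)
  if (check_paths) {
    base <- dirname(path)
    resolved <- ifelse(grepl("^(/|[A-Za-z]:)", d$timeseries_path),
                       d$timeseries_path, file.path(base, d$timeseries_path))
    missing <- resolved[!file.exists(resolved)]
    if (length(missing)) {
      stop_megconn(sprintf("time-series file(s) not found: %s",
                           paste(missing, collapse = ", ")),
                   "megconn_validation_error")
    }
    d$timeseries_path <- resolved
  }
  d
}

#' Export a simulated cohort to disk
#'
#' Writes one time-series file per subject (the raw recording reassembled
#' from the subject's epochs is not available, so the concatenated epoch data
#' at the epoch sampling rate is written) plus a manifest referencing the
#' files with per-epoch quality scores.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    data <- do.call(cbind, lapply(s$epochs, function(e) e$data))
    ts <- roi_ts(data, s$epochs[[1L]]$fs, s$epochs[[1L]]$labels)
    fname <- paste0(s$subject_id, ".tsv")
    write_timeseries(ts, file.path(dir, fname))
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               mmse = s$mmse, timeseries_path = fname,
               quality_scores = paste(vapply(s$epochs, function(e) e$quality,
                                             integer(1)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' Reads each subject's time series, optionally downsamples, segments into
#' epochs, and attaches the manifest's quality scores (recycled checks: the
#' score count must match the epoch count).
#'
#' @param manifest_path Path to a manifest (see [read_manifest()]).
#' @param downsample_factor Decimation factor applied before segmentation
#'   (default 1: files exported by [export_cohort()] are already at the
#'   analysis rate).
#' @param epoch_samples Samples per epoch.
#' @param name Cohort name.
#' @return A `cohort`.
#' @export
load_cohort <- function(manifest_path, downsample_factor = 1L,
                        epoch_samples = 4096L, name = "loaded") {
  man <- read_manifest(manifest_path)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    ts <- read_timeseries(man$timeseries_path[i])
    if (downsample_factor > 1L) ts <- downsample(ts, downsample_factor)
    epochs <- segment_epochs(ts, epoch_samples)
    qs <- man$quality_scores[[i]]
    if (length(qs) != length(epochs)) {
      stop_megconn(sprintf("%s: %d quality scores for %d epochs",
                           man$subject_id[i], length(qs), length(epochs)),
                   "megconn_validation_error")
    }
    for (k in seq_along(epochs)) epochs[[k]]$quality <- qs[k]
    subject_record(man$subject_id[i], man$group[i], man$age[i],
                   man$mmse[i], epochs)
  })
  structure(list(subjects = subjects, name = name), class = "cohort")
}

#' Write result tables
#'
#' Writes each named table as a tab-separated file with a deterministic column
#' order plus a `run_log.txt` recording the package version and seed, so a
#' rerun with identical inputs reproduces the outputs byte for byte.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the run log.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NA) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("megconn version: %s", as.character(utils::packageVersion("megconn"))),
    sprintf("seed: %s", seed),
    sprintf("tables: %s", paste(sprintf("%s[%d rows]", names(tables),
                                        vapply(tables, nrow, integer(1))),
                                collapse = ", "))
  ), log_path)
  invisible(c(paths, log_path))
}
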