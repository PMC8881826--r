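# Split-sample reproducibility harness: random diagnosis-stratified halving of
# a pooled cohort, independent group contrasts in each half, and concordance
# tallies across repeated splits. An effect counts as reproduced only when it
# is significant in both halves with the same sign of the standardized beta.

subjects_frame <- function(x) {
  if (inherits(x, "cohort")) {
    data.frame(
      subject_id = vapply(x$subjects, function(s) s$subject_id, character(1)),
      group = vapply(x$subjects, function(s) s$group, character(1)),
      stringsAsFactors = FALSE)
  } else {
    d <- unique(as.data.frame(x)[, c("subject_id", "group")])
    rownames(d) <- NULL
    d
  }
}

#' Random stratified split of a cohort
#'
#' Partitions subjects into a test and a validation half, stratified by
#' diagnosis: each group is randomly permuted and its first `ceiling(m / 2)`
#' members go to the test half, so per-group imbalance is at most one subject.
#'
#' @param x A `cohort`, or a data.frame with `subject_id` and `group` columns
#'   (e.g. a cohort FC table).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param split_id Identifier recorded in the plan.
#' @return A `split_plan`: list with `split_id`, `seed`, `test_ids`,
#'   `validation_ids`.
#' @export
split_cohort <- function(x, seed = NULL, split_id = 1L) {
  d <- subjects_frame(x)
  counts <- table(d$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop_megconn("each group needs >= 2 subjects to split", "megconn_invalid_input")
  }
  local_seed(seed, {
    test_ids <- character(0)
    for (g in names(counts)) {
      ids <- d$subject_id[d$group == g]
      ids <- sample(ids)
      test_ids <- c(test_ids, ids[seq_len(ceiling(length(ids) / 2))])
    }
    structure(list(split_id = split_id, seed = seed,
                   test_ids = sort(test_ids),
                   validation_ids = sort(setdiff(d$subject_id, test_ids))),
              class = "split_plan")
  })
}

#' Evaluate one split
#'
#' Fits the plain GLM group contrast independently in each half for every
#' metric x band of the subject-level results and flags effects reproduced at
#' level `alpha` with matching beta sign. A half in which a contrast is
#' degenerate (a missing group or constant outcome) is flagged and that cell
#' excluded.
#'
#' @param plan A `split_plan`.
#' @param subject_results data.frame with subject_id, group, metric, band,
#'   global_fc (one row per subject x metric x band).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per metric x band: split_id, betas and
#'   p-values in both halves, `sign_agree`, `reproduced`, `valid`.
#' @export
evaluate_split <- function(plan, subject_results, alpha = 0.05) {
  stopifnot(inherits(plan, "split_plan"))
  missing_ids <- setdiff(c(plan$test_ids, plan$validation_ids),
                         subject_results$subject_id)
  if (length(missing_ids)) {
    stop_megconn("subject results missing for some subjects in the plan",
                 "megconn_invalid_input")
  }
  cells <- unique(subject_results[, c("metric", "band")])
  fit_half <- function(ids, metric, band) {
    d <- subject_results[subject_results$subject_id %in% ids &
                           subject_results$metric == metric &
                           subject_results$band == band, ]
    tryCatch(glm_group(d$global_fc, d$group), megconn_error = function(e) NULL)
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ft <- fit_half(plan$test_ids, cells$metric[i], cells$band[i])
    fv <- fit_half(plan$validation_ids, cells$metric[i], cells$band[i])
    valid <- !is.null(ft) && !is.null(fv)
    beta_t <- if (valid) ft$beta_std else NA_real_
    beta_v <- if (valid) fv$beta_std else NA_real_
    p_t <- if (valid) ft$p_value else NA_real_
    p_v <- if (valid) fv$p_value else NA_real_
    sign_agree <- valid && sign(beta_t) == sign(beta_v)
    data.frame(split_id = plan$split_id, metric = cells$metric[i],
               band = cells$band[i], beta_test = beta_t, p_test = p_t,
               beta_validation = beta_v, p_validation = p_v,
               sign_agree = sign_agree,
               reproduced = valid && p_t < alpha && p_v < alpha && sign_agree,
               valid = valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multi-split reproducibility report
#'
#' Draws `n_splits` independent stratified split plans (seeds derived from the
#' master seed), evaluates each, and tallies per metric x band how often the
#' group effect reproduced, along with split-averaged effect sizes.
#'
#' @param subject_results data.frame as for [evaluate_split()].
#' @param n_splits Number of splits (default 6: the original allocation plus
#'   five additional random iterations).
#' @param seed Integer master seed.
#' @param alpha Significance level.
#' @return A `repro_report`: list with `per_split` (row per split x metric x
#'   band) and `summary` (row per metric x band with `n_reproduced`,
#'   `n_valid_splits`, mean betas).
#' @export
multi_split <- function(subject_results, n_splits = 6L, seed = NULL,
                        alpha = 0.05) {
  stopifnot(is_count(n_splits))
  seed <- seed %||% 1L
  per_split <- do.call(rbind, lapply(seq_len(n_splits), function(k) {
    plan <- split_cohort(subject_results, seed = derive_seed(seed, k),
                         split_id = k)
    evaluate_split(plan, subject_results, alpha = alpha)
  }))
  cells <- unique(per_split[, c("metric", "band")])
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- per_split[per_split$metric == cells$metric[i] &
                     per_split$band == cells$band[i] & per_split$valid, ]
    data.frame(metric = cells$metric[i], band = cells$band[i],
               n_reproduced = sum(d$reproduced), n_valid_splits = nrow(d),
               mean_beta_test = mean(d$beta_test),
               mean_beta_validation = mean(d$beta_validation),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_split = per_split, summary = summary, alpha = alpha,
                 n_splits = n_splits),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> %d splits, alpha = %g\n", x$n_splits, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
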