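# Group-level statistics: normality gating (identity / log / rank), GLM group
# contrasts with standardized betas and optional covariates, rank-based
# fallback, regional Mann-Whitney tests with Benjamini-Hochberg correction,
# and Spearman correlations (global FC vs MMSE; matrix-vs-matrix).

#' Normality gate
#'
#' Automated stand-in for visual normality checks: a Shapiro-Wilk test at
#' `alpha` on the raw values; if violated and the values are strictly
#' positive, the log-transformed values are retested; if still violated (or
#' log is unavailable), the mid-rank transform is selected.
#'
#' @param values Numeric vector, n >= 8.
#' @param alpha Significance level of the Shapiro-Wilk test (default 0.05).
#' @return List with `transform` (`"identity"`, `"log"`, or `"rank"`),
#'   `values` (transformed), and `shapiro_p` (p-value at the accepted stage,
#'   `NA` for rank).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 8L) {
    stop_megconn("normality gate needs n >= 8", "megconn_invalid_input")
  }
  p_raw <- tryCatch(stats::shapiro.test(values)$p.value, error = function(e) 0)
  if (is.finite(p_raw) && p_raw >= alpha) {
    return(list(transform = "identity", values = values, shapiro_p = p_raw))
  }
  if (all(values > 0)) {
    lv <- log(values)
    p_log <- tryCatch(stats::shapiro.test(lv)$p.value, error = function(e) 0)
    if (is.finite(p_log) && p_log >= alpha) {
      return(list(transform = "log", values = lv, shapiro_p = p_log))
    }
  }
  list(transform = "rank", values = rank(values, ties.method = "average"),
       shapiro_p = NA_real_)
}

code_group <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("AD", "SCD"))
  if (length(bad)) {
    stop_megconn(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
                 "megconn_invalid_input")
  }
  if (length(unique(group)) < 2L) {
    stop_megconn("both groups must be represented", "megconn_invalid_input")
  }
  ifelse(group == "AD", 1, 0)  # SCD = 0, AD = 1: negative beta = lower FC in AD
}

#' GLM group contrast with standardized beta
#'
#' Ordinary least squares of the z-scored outcome on the z-scored group code
#' (SCD = 0, AD = 1) and z-scored covariates. The group coefficient is the
#' standardized beta (for the single-predictor model it equals the
#' point-biserial correlation, so |beta| <= 1); its two-sided t-test gives
#' the p-value. Group means and SDs are reported on the original scale.
#'
#' @param fc Numeric outcome vector (e.g. global FC per subject).
#' @param group Character vector of `"AD"` / `"SCD"` labels.
#' @param covariates Optional numeric matrix or data.frame of covariates.
#' @param model Tag recorded in the result (`"plain"` by default).
#' @param raw Optional outcome on the original scale for the reported means
#'   (used by the log/rank wrappers); defaults to `fc`.
#' @return One-row data.frame: n_scd, n_ad, mean_scd, sd_scd, mean_ad, sd_ad,
#'   beta_std, p_value, model.
#' @export
glm_group <- function(fc, group, covariates = NULL, model = "plain", raw = fc) {
  g <- code_group(group)
  if (length(fc) != length(g)) {
    stop_megconn("`fc` and `group` lengths differ", "megconn_invalid_input")
  }
  if (stats::sd(fc) == 0) {
    stop_megconn("constant outcome: degenerate model", "megconn_degenerate")
  }
  d <- data.frame(.y = zscore(fc), .group = zscore(g))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(fc)) {
      stop_megconn("covariate rows must match outcome length", "megconn_invalid_input")
    }
    cz <- apply(covariates, 2L, zscore)
    colnames(cz) <- paste0(".c", seq_len(ncol(cz)))
    d <- cbind(d, as.data.frame(cz))
  }
  if (length(fc) <= ncol(d)) {
    stop_megconn("too few observations for the number of predictors", "megconn_invalid_input")
  }
  fit <- stats::lm(.y ~ ., data = d)
  sm <- summary(fit)$coefficients
  data.frame(
    n_scd = sum(g == 0), n_ad = sum(g == 1),
    mean_scd = mean(raw[g == 0]), sd_scd = stats::sd(raw[g == 0]),
    mean_ad = mean(raw[g == 1]), sd_ad = stats::sd(raw[g == 1]),
    beta_std = unname(sm[".group", "Estimate"]),
    p_value = unname(sm[".group", "Pr(>|t|)"]),
    model = model, stringsAsFactors = FALSE)
}

#' Rank-based GLM group contrast (ANOVA on ranks)
#'
#' Replaces the outcome by mid-ranks and applies [glm_group()]; used for
#' variables that cannot be normalized by a log transform. Reported group
#' means/SDs stay on the original scale.
#'
#' @inheritParams glm_group
#' @return One-row data.frame as for [glm_group()], with `model = "rank"`.
#' @export
rank_glm_group <- function(fc, group, covariates = NULL) {
  glm_group(rank(fc, ties.method = "average"), group, covariates,
            model = "rank", raw = fc)
}

#' Regional Mann-Whitney comparisons with FDR correction
#'
#' Two-sided Mann-Whitney U test (tie-corrected normal approximation) per ROI
#' comparing AD vs SCD strengths, followed by Benjamini-Hochberg correction
#' across the ROI family.
#'
#' @param strengths_ad `n_ad x n_roi` matrix of ROI strengths.
#' @param strengths_scd `n_scd x n_roi` matrix.
#' @param q FDR level (default 0.05).
#' @return data.frame with columns roi, U, p, q_value, significant.
#' @export
mwu_regional <- function(strengths_ad, strengths_scd, q = 0.05) {
  strengths_ad <- as.matrix(strengths_ad)
  strengths_scd <- as.matrix(strengths_scd)
  if (ncol(strengths_ad) != ncol(strengths_scd)) {
    stop_megconn("ROI counts differ between groups", "megconn_invalid_input")
  }
  if (nrow(strengths_ad) < 2L || nrow(strengths_scd) < 2L) {
    stop_megconn("need >= 2 subjects per group", "megconn_invalid_input")
  }
  n_roi <- ncol(strengths_ad)
  U <- p <- numeric(n_roi)
  for (r in seq_len(n_roi)) {
    a <- strengths_ad[, r]; s <- strengths_scd[, r]
    if (stats::sd(c(a, s)) == 0) {
      U[r] <- length(a) * length(s) / 2; p[r] <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, s, exact = FALSE, correct = FALSE))
      U[r] <- unname(wt$statistic)
      p[r] <- wt$p.value
    }
  }
  adj <- fdr_bh(p, q)
  roi <- colnames(strengths_ad) %||% paste0("ROI_", seq_len(n_roi))
  data.frame(roi = roi, U = U, p = p, q_value = adj$q_values,
             significant = adj$reject, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment; a hypothesis is rejected iff its adjusted value is
#' at most `q`.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `q_values` (BH-adjusted p-values) and `reject` (logical).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(list(q_values = numeric(0), reject = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop_megconn("p-values must lie in [0, 1]", "megconn_invalid_input")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(q_values = adj, reject = adj <= q)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with the t approximation for the p-value
#' (dof = n - 2).
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return List with `rho`, `p`, `df`, `n`.
#' @export
spearman_rho <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 3L) {
    stop_megconn("need equal-length vectors with n >= 3", "megconn_invalid_input")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_megconn("correlation undefined for a constant vector", "megconn_degenerate")
  }
  rho <- stats::cor(rank(a, ties.method = "average"),
                    rank(b, ties.method = "average"))
  df <- n - 2L
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(rho = rho, p = p, df = df, n = n)
}

#' Correlation between two connectivity matrices
#'
#' Spearman correlation between matrices of the same metric/band and ROI
#' ordering, either over the 4005 strictly-upper-triangle entries
#' (`"upper_triangle"`) or over the 90 row-mean strengths (`"roi_strength"`).
#' Both modes are reported with their own n and dof since published matrix
#' correlations are sometimes quoted with strength-level degrees of freedom.
#'
#' @param mat_a,mat_b `conn_matrix` objects (or plain matrices with matching
#'   dimnames).
#' @param mode `"upper_triangle"` or `"roi_strength"`.
#' @return data.frame with mode, rho, p, n_pairs, df.
#' @export
matrix_correlation <- function(mat_a, mat_b,
                               mode = c("upper_triangle", "roi_strength")) {
  mode <- match.arg(mode)
  if (!identical(dim(mat_a), dim(mat_b)) ||
      !identical(rownames(mat_a), rownames(mat_b))) {
    stop_megconn("matrices must share dimensions and ROI labels", "megconn_invalid_input")
  }
  if (mode == "upper_triangle") {
    a <- mat_a[upper.tri(mat_a)]
    b <- mat_b[upper.tri(mat_b)]
  } else {
    a <- roi_strength(mat_a)
    b <- roi_strength(mat_b)
  }
  s <- spearman_rho(a, b)
  data.frame(mode = mode, rho = s$rho, p = s$p, n_pairs = s$n, df = s$df,
             stringsAsFactors = FALSE)
}

#' Global group-contrast table
#'
#' For every metric x band in a cohort FC table: gate the outcome through the
#' normality check (identity / log / rank), fit the corresponding GLM group
#' contrast, and report means, standardized beta and p. One row per metric x
#' band, in the style of a global-analysis results table.
#'
#' @param fc_tab Output of [cohort_fc_table()].
#' @param covariates Character vector of covariate column names in `fc_tab`
#'   (e.g. `"age"`, `"rel_power"`), or NULL for the plain model.
#' @param gate Apply the normality gate (default TRUE); when FALSE the plain
#'   identity-scale GLM is always used.
#' @return data.frame with one row per metric x band.
#' @export
global_group_table <- function(fc_tab, covariates = NULL, gate = TRUE) {
  needed <- c("subject_id", "group", "metric", "band", "global_fc")
  if (!all(needed %in% names(fc_tab))) {
    stop_megconn("fc_tab lacks required columns", "megconn_invalid_input")
  }
  cells <- unique(fc_tab[, c("metric", "band")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- fc_tab$metric == cells$metric[i] & fc_tab$band == cells$band[i]
    d <- fc_tab[sel, ]
    covs <- if (!is.null(covariates)) as.matrix(d[, covariates, drop = FALSE])
    fc <- d$global_fc
    res <- if (!gate) {
      glm_group(fc, d$group, covs)
    } else {
      ng <- normality_gate(fc)
      switch(ng$transform,
        identity = glm_group(fc, d$group, covs),
        log = glm_group(ng$values, d$group, covs, model = "log", raw = fc),
        rank = rank_glm_group(fc, d$group, covs))
    }
    cbind(metric = cells$metric[i], band = cells$band[i], res,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of global FC with MMSE
#'
#' Computed within the AD group only (pooling both halves of a split design),
#' uncorrected for multiple comparisons; subjects with missing MMSE are
#' dropped.
#'
#' @param fc_tab Output of [cohort_fc_table()] (must contain `mmse`).
#' @return data.frame with one row per metric x band: rho, p, df, n.
#' @export
mmse_correlations <- function(fc_tab) {
  d <- fc_tab[fc_tab$group == "AD" & !is.na(fc_tab$mmse), ]
  cells <- unique(d[, c("metric", "band")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- d$metric == cells$metric[i] & d$band == cells$band[i]
    s <- spearman_rho(d$global_fc[sel], d$mmse[sel])
    data.frame(metric = cells$metric[i], band = cells$band[i],
               rho = s$rho, p = s$p, df = s$df, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
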