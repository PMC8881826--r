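test_that("normality gate selects identity, log, or rank as distributions demand", {
  set.seed(61)
  gauss <- rnorm(100, 0.5, 0.01)
  expect_equal(normality_gate(gauss)$transform, "identity")
  lgn <- exp(rnorm(200, 0, 1.5))
  g_log <- normality_gate(lgn)
  expect_equal(g_log$transform, "log")
  expect_equal(g_log$values, log(lgn))
  heavy <- c(rcauchy(150), -1e6, 1e6)  # not normal, not log-normalizable
  g_rank <- normality_gate(heavy)
  expect_equal(g_rank$transform, "rank")
  expect_equal(g_rank$values, rank(heavy, ties.method = "average"))
  expect_error(normality_gate(rnorm(5)), class = "megconn_invalid_input")
})

test_that("standardized beta equals the point-biserial correlation without covariates", {
  set.seed(62)
  group <- rep(c("SCD", "AD"), c(29, 28))
  g <- ifelse(group == "AD", 1, 0)
  fc <- rnorm(57, mean = 0.52 - 0.01 * g, sd = 0.015)
  res <- glm_group(fc, group)
  # closed-form oracle: Pearson correlation between outcome and group code
  expect_equal(res$beta_std, cor(fc, g), tolerance = 1e-10)
  expect_lte(abs(res$beta_std), 1)
  expect_equal(res$n_scd, 29L)
  expect_equal(res$n_ad, 28L)
  expect_equal(res$mean_ad, mean(fc[g == 1]))
  # perfect association: outcome equal to the z-scored group code
  z <- (g - mean(g)) / sd(g)
  expect_equal(suppressWarnings(glm_group(z, group)$beta_std), 1,
               tolerance = 1e-10)
})

test_that("beta is antisymmetric under swapping the group labels", {
  set.seed(63)
  group <- rep(c("SCD", "AD"), each = 20)
  fc <- rnorm(40)
  flipped <- ifelse(group == "AD", "SCD", "AD")
  expect_equal(glm_group(fc, group)$beta_std,
               -glm_group(fc, flipped)$beta_std, tolerance = 1e-12)
})

test_that("null GLM p-values are uniform", {
  set.seed(64)
  group <- rep(c("SCD", "AD"), each = 25)
  pvals <- replicate(200, glm_group(rnorm(50), group)$p_value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.05)
})

test_that("a covariate independent of group and outcome barely moves the beta", {
  set.seed(65)
  group <- rep(c("SCD", "AD"), each = 200)
  fc <- rnorm(400) + 0.3 * (group == "AD")
  noise_cov <- rnorm(400)
  b0 <- glm_group(fc, group)$beta_std
  b1 <- glm_group(fc, group, covariates = cbind(noise_cov))$beta_std
  expect_lt(abs(b1 - b0), 0.05)
})

test_that("rank GLM is invariant to monotone transforms and matches Wilcoxon", {
  set.seed(66)
  group <- rep(c("SCD", "AD"), each = 15)
  fc <- rnorm(30) + 0.8 * (group == "AD")
  r1 <- rank_glm_group(fc, group)
  r2 <- rank_glm_group(exp(3 * fc), group)
  expect_equal(r1$beta_std, r2$beta_std, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$model, "rank")
  # agreement with the rank-sum normal approximation across simulations
  diffs <- replicate(200, {
    y <- rnorm(30) + sample(c(0, 0.5), 1) * (group == "AD")
    pw <- suppressWarnings(wilcox.test(y[group == "AD"], y[group == "SCD"],
                                       exact = FALSE, correct = FALSE)$p.value)
    rank_glm_group(y, group)$p_value - pw
  })
  expect_lt(mean(abs(diffs)), 0.02)
})

test_that("rank GLM uses mid-ranks for ties (hand-ranked example)", {
  group <- rep(c("SCD", "AD"), each = 3)
  fc <- c(1, 2, 2, 3, 3, 10)
  hand_ranks <- c(1, 2.5, 2.5, 4.5, 4.5, 6)
  expect_equal(rank_glm_group(fc, group)$beta_std,
               glm_group(hand_ranks, group)$beta_std, tolerance = 1e-12)
})

test_that("Mann-Whitney on fully separated tiny groups matches exact enumeration", {
  ad <- matrix(c(1, 2, 3), ncol = 1)
  scd <- matrix(c(4, 5, 6), ncol = 1)
  res <- mwu_regional(ad, scd)
  expect_equal(res$U, 0)
  # oracle: all 20 label assignments of {1..6} into two triples
  expect_equal(mwu_exact_enumeration(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(suppressWarnings(
    wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value), 0.1)
})

test_that("regional Mann-Whitney with FDR flags a planted shift and only that", {
  set.seed(67)
  n_roi <- 20
  ad <- matrix(rnorm(28 * n_roi), 28)
  scd <- matrix(rnorm(29 * n_roi), 29)
  ad[, 7] <- ad[, 7] + 2  # large planted shift in one region
  res <- mwu_regional(ad, scd)
  expect_true(res$significant[7])
  expect_lt(sum(res$significant[-7]), 3)
  expect_true(all(res$q_value >= res$p - 1e-12))
  # all-tied region gives p = 1
  ad2 <- cbind(ad[, 1:2] * 0 + 1); scd2 <- cbind(scd[, 1:2] * 0 + 1)
  res2 <- mwu_regional(ad2, scd2)
  expect_equal(res2$p, c(1, 1))
})

test_that("Benjamini-Hochberg matches the hand step-up rule", {
  # thresholds i*q/m = 0.0125, 0.025, 0.0375, 0.05: all four rejected
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_false(any(fdr_bh(rep(1, 6))$reject))
  expect_true(fdr_bh(0.04, q = 0.05)$reject)
  set.seed(68)
  for (k in 1:20) {
    p <- runif(15)^sample(1:3, 1)
    r <- fdr_bh(p, 0.05)
    expect_equal(r$reject, bh_stepup_reject(p, 0.05))
    # sandwiched between uncorrected and Bonferroni rejection counts
    expect_lte(sum(r$reject), sum(p <= 0.05))
    expect_gte(sum(r$reject), sum(p <= 0.05 / length(p)))
  }
  expect_length(fdr_bh(numeric(0))$reject, 0L)
})

test_that("Spearman correlation handles monotone extremes and reports dof n - 2", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  s <- spearman_rho(rnorm(55), rnorm(55))
  expect_equal(s$df, 53L)
  set.seed(69)
  a <- sample(1:8, 30, replace = TRUE); b <- a + rnorm(30)
  expect_equal(spearman_rho(a, b)$rho,
               unname(cor.test(a, b, method = "spearman", exact = FALSE)$estimate),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), class = "megconn_degenerate")
})

test_that("matrix correlations use the upper triangle or ROI strengths", {
  set.seed(70)
  n <- 12
  a <- matrix(runif(n^2), n); a <- (a + t(a)) / 2; diag(a) <- 0
  dimnames(a) <- list(paste0("R", 1:n), paste0("R", 1:n))
  b <- a^2  # monotone transform
  r_ut <- matrix_correlation(a, b, "upper_triangle")
  expect_equal(r_ut$rho, 1)
  expect_equal(r_ut$n_pairs, n * (n - 1) / 2)
  expect_equal(r_ut$df, n * (n - 1) / 2 - 2)
  r_rs <- matrix_correlation(a, b, "roi_strength")
  expect_equal(r_rs$n_pairs, n)
  expect_equal(r_rs$df, n - 2)
  expect_equal(matrix_correlation(a, a, "roi_strength")$rho, 1)
  c_mat <- a; rownames(c_mat) <- paste0("X", 1:n)
  expect_error(matrix_correlation(a, c_mat), class = "megconn_invalid_input")
  # independent matrices decorrelate
  set.seed(71)
  d <- matrix(runif(n^2), n); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- dimnames(a)
  expect_lt(abs(matrix_correlation(a, d, "upper_triangle")$rho),
            4 / sqrt(n * (n - 1) / 2))
})

test_that("the global group table gates each metric-band cell and tags the model", {
  set.seed(72)
  subj <- sprintf("S%02d", 1:40)
  group <- rep(c("SCD", "AD"), each = 20)
  tab <- rbind(
    data.frame(subject_id = subj, group = group, metric = "aec_c", band = "beta",
               global_fc = rnorm(40, 0.52, 0.01) - 0.012 * (group == "AD")),
    data.frame(subject_id = subj, group = group, metric = "pli", band = "theta",
               global_fc = rnorm(40, 0.10, 0.005) + 0.006 * (group == "AD")))
  out <- global_group_table(tab)
  expect_equal(nrow(out), 2L)
  expect_true(all(c("beta_std", "p_value", "model", "mean_ad", "sd_scd") %in% names(out)))
  beta_row <- out[out$metric == "aec_c", ]
  expect_lt(beta_row$beta_std, 0)
  theta_row <- out[out$metric == "pli", ]
  expect_gt(theta_row$beta_std, 0)
})

test_that("MMSE correlations are computed in the AD group only", {
  set.seed(73)
  n <- 30
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    group = rep(c("AD", "SCD"), each = n / 2),
                    metric = "aec_c", band = "alpha",
                    mmse = c(sample(12:29, n / 2, TRUE), sample(24:30, n / 2, TRUE)),
                    global_fc = rnorm(n))
  tab$mmse[2] <- NA  # missing MMSE excluded
  out <- mmse_correlations(tab)
  expect_equal(out$n, n / 2 - 1)
  expect_equal(out$df, n / 2 - 3)
})
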