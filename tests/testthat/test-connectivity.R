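test_that("PLI limits: constant non-zero lag gives 1, zero lag gives 0", {
  p <- runif(4096, -pi, pi)
  expect_identical(pli_pair(p, p - pi / 4), 1)
  expect_identical(pli_pair(p, p), 0)
  # alternating +pi/3 / -pi/3 in equal counts cancels
  dphi <- rep(c(pi / 3, -pi / 3), 50)
  expect_identical(pli_pair(dphi, numeric(100)), 0)
  expect_error(pli_pair(1:3, 1:4), class = "megconn_invalid_input")
})

test_that("PLI of i.i.d. uniform phase differences matches the sign-sum null", {
  set.seed(31)
  n <- 4096
  signed <- replicate(1000, mean(sign(sin(runif(n, -pi, pi)))))
  expect_lt(abs(mean(signed)), 4 * sd(signed) / sqrt(1000))
  expect_equal(sd(signed), 1 / sqrt(n), tolerance = 0.1)
  # and the packaged metric is the absolute value of that statistic
  set.seed(31)
  dphi <- runif(n, -pi, pi)
  expect_identical(pli_pair(dphi, numeric(n)), abs(mean(sign(sin(dphi)))))
})

test_that("vectorized PLI equals a per-sample accumulation loop exactly", {
  set.seed(32)
  for (k in 1:100) {
    px <- runif(512, -pi, pi)
    py <- runif(512, -pi, pi)
    acc <- 0
    for (t in seq_along(px)) acc <- acc + sign(sin(px[t] - py[t]))
    expect_identical(pli_pair(px, py), abs(acc / length(px)))
  }
})

test_that("PLI is invariant to amplitude scaling of either signal", {
  set.seed(33)
  fs <- 312.5
  x <- fft_bandpass(rnorm(2048), "alpha", fs)
  y <- fft_bandpass(rnorm(2048), "alpha", fs)
  ph <- function(s) phase_envelope(s)$phase
  expect_equal(pli_pair(ph(3 * x), ph(0.1 * y)), pli_pair(ph(x), ph(y)),
               tolerance = 1e-12)
  expect_equal(pli_pair(ph(x), ph(y)), pli_pair(ph(y), ph(x)), tolerance = 1e-12)
})

test_that("orthogonalization removes the zero-lag component exactly", {
  set.seed(34)
  x <- rnorm(1000)
  expect_lt(sqrt(mean(orthogonalize_pair(x, 2 * x)^2)), 1e-10 * sqrt(mean((2 * x)^2)))
  # y orthogonal to x in sample: residual = y - mean(y)
  y <- rnorm(1000)
  y_perp <- orthogonalize_pair(x, y) # exactly uncorrelated with x by construction
  expect_lt(abs(cor(y_perp, x)), 1e-10)
  expect_equal(orthogonalize_pair(x, y_perp + 5), y_perp - mean(y_perp),
               tolerance = 1e-10)
  # y = x + n: residual recovers n up to the sample projection
  # (oracle: explicit normal-equations solve)
  n_noise <- rnorm(1000)
  y2 <- x + n_noise
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(orthogonalize_pair(x, y2), as.numeric(y2 - X %*% beta),
               tolerance = 1e-10)
  expect_error(orthogonalize_pair(rep(2, 10), rnorm(10)), class = "megconn_degenerate")
})

test_that("AEC rescaling maps correlation extremes to 1, 0, and 0.5", {
  set.seed(35)
  e <- abs(rnorm(500)) + 0.1
  expect_equal(aec_pair(e, e), 1)
  expect_equal(aec_pair(e, -e + 10), 0)
  vals <- replicate(200, aec_pair(abs(rnorm(500)) + 0.1, abs(rnorm(500)) + 0.1))
  expect_lt(abs(mean(vals) - 0.5), 3 * sd(vals) / sqrt(200))
  expect_error(aec_pair(rep(1, 10), e[1:10]), class = "megconn_degenerate")
})

test_that("AEC-c is symmetric, scale-invariant, and rejects collinear pairs", {
  set.seed(36)
  fs <- 312.5
  x <- fft_bandpass(rnorm(2048), "beta", fs)
  y <- fft_bandpass(rnorm(2048), "beta", fs)
  expect_equal(aec_c_pair(x, y), aec_c_pair(y, x), tolerance = 1e-12)
  expect_equal(aec_c_pair(5 * x + 2, y), aec_c_pair(x, y), tolerance = 1e-8)
  expect_error(aec_c_pair(x, x), class = "megconn_degenerate")
  # envelope-level orthogonalization variant runs and stays in [0, 1]
  v <- aec_c_pair(x, y, on = "envelope")
  expect_true(v >= 0 && v <= 1)
})

test_that("AEC-c sees a shared envelope modulator that AEC-style leakage cannot fake", {
  # shared slow modulator on independent carriers: AEC-c well above 0.5
  set.seed(37)
  vals <- replicate(30, {
    ep <- first_epoch(envelope_config(0.9), seed = sample.int(1e6, 1))
    connectivity_matrix(ep, "beta", "aec_c")[1, 2]
  })
  expect_gt(mean(vals), 0.55)
})

test_that("connectivity matrices are symmetric with zero diagonal and find planted pairs", {
  cfg <- sim_config(n_roi = 4, duration = 14, noise_amplitude = 0.5,
                    band_oscillations = data.frame(band = "alpha", freq = 10,
                                                   amplitude = 2),
                    phase_coupling = list(list(pairs = rbind(c(2, 3)),
                                               band = "alpha", lag = pi / 4,
                                               strength = 0.9)))
  ep <- first_epoch(cfg, seed = 38)
  m <- connectivity_matrix(ep, "alpha", "pli")
  expect_equal(dim(m), c(4L, 4L))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m[2, 3], max(m))
})

test_that("degenerate pairs fall back to the metric null and are counted", {
  set.seed(39)
  x <- fft_bandpass(rnorm(1024), "alpha", 250)
  y <- fft_bandpass(rnorm(1024), "alpha", 250)
  ep <- as_epoch(rbind(x, x, y), 250)  # channels 1 and 2 identical
  m <- connectivity_matrix(ep, "alpha", "aec_c")
  expect_equal(m[1, 2], 0.5)
  expect_equal(attr(m, "n_degenerate"), 1L)
  expect_lt(max(abs(m - t(m))), 1e-12)
})

test_that("ROI strength averages each row excluding the diagonal", {
  m <- matrix(0.3, 5, 5); diag(m) <- 0
  expect_equal(unname(roi_strength(m)), rep(0.3, 5))
  expect_equal(global_fc(m), 0.3)
  # planted single pair at value v: strengths v/(n-1) at its ROIs, 0 elsewhere
  v <- 0.8
  m2 <- matrix(0, 5, 5); m2[2, 4] <- m2[4, 2] <- v
  expect_equal(unname(roi_strength(m2)), c(0, v / 4, 0, v / 4, 0))
  # global FC invariant under simultaneous row/column permutation
  p <- c(3, 1, 5, 2, 4)
  set.seed(40)
  m3 <- matrix(runif(25), 5, 5); m3 <- (m3 + t(m3)) / 2; diag(m3) <- 0
  expect_equal(global_fc(m3[p, p]), global_fc(m3))
})

test_that("subject-level connectivity is the element-wise epoch mean", {
  set.seed(41)
  x <- fft_bandpass(rnorm(1024), "alpha", 250)
  y <- fft_bandpass(rnorm(1024), "alpha", 250)
  ep <- as_epoch(rbind(x, y), 250)
  eps <- lapply(1:10, function(i) { e <- ep; e$index <- i; e })
  subj <- structure(list(subject_id = "S1", group = "SCD", age = 60, mmse = 28,
                         epochs = eps), class = "subject_record")
  res <- subject_connectivity(subj, "alpha", "pli", n_epochs = 10L)
  single <- connectivity_matrix(ep, "alpha", "pli")
  expect_equal(unclass(res$matrix), unclass(single), tolerance = 1e-12)
  # subject global FC is the arithmetic mean of the epoch-level global FCs
  set.seed(42)
  eps2 <- lapply(1:4, function(i) {
    as_epoch(rbind(fft_bandpass(rnorm(1024), "alpha", 250),
                   fft_bandpass(rnorm(1024), "alpha", 250)), 250, index = i)
  })
  subj2 <- structure(list(subject_id = "S2", group = "AD", age = 70, mmse = 20,
                          epochs = eps2), class = "subject_record")
  res2 <- subject_connectivity(subj2, "alpha", "pli", n_epochs = 4L)
  per_epoch <- vapply(eps2, function(e)
    global_fc(connectivity_matrix(e, "alpha", "pli")), numeric(1))
  expect_equal(res2$global_fc, mean(per_epoch), tolerance = 1e-12)
})
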