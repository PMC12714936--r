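test_that("total hemoglobin is the elementwise chromophore sum", {
  expect_equal(total_hemoglobin(1.2, -0.4), 0.8)
  set.seed(1)
  a <- matrix(stats::rnorm(60), 6)
  b <- matrix(stats::rnorm(60), 6)
  want <- a
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    want[i, j] <- a[i, j] + b[i, j]
  expect_equal(total_hemoglobin(a, b), want)
  expect_equal(total_hemoglobin(a, -a), matrix(0, 6, 10))
  expect_error(total_hemoglobin(a, b[, 1:5]), "identical shapes")
})

test_that("moving-average smoothing has the expected kernel and variance law", {
  fs <- 25  # 200 ms window -> 5 samples
  x <- rep(4.2, 100)
  expect_equal(smooth_series(x, 200, sample_rate = fs), x)
  imp <- c(rep(0, 50), 1, rep(0, 49))
  sm <- smooth_series(imp, 200, sample_rate = fs)
  expect_equal(sm[49:53], rep(0.2, 5))
  expect_equal(sum(sm), 1)
  set.seed(3)
  noise <- stats::rnorm(20000)
  ratio <- stats::var(smooth_series(noise, 200, sample_rate = fs)) /
    stats::var(noise)
  expect_equal(ratio, 1 / 5, tolerance = 0.2)
})

test_that("block epoching returns percent change from the pre-stimulus baseline", {
  fs <- 10
  n <- 920
  const <- time_series_recording(matrix(5, 2, n), fs, c("a", "b"),
                                 events = build_warble_protocol(),
                                 modality = "fnirs_raw")
  ep <- epoch_blocks(const)
  expect_equal(nrow(ep$epochs), 3 * 2)  # 3 onsets x 2 channels
  expect_true(all(ep$epochs == 0))
  # injected -2% response: epoch minimum ~ -2
  tr <- hemo_truth(channel_betas = -0.02, cardiac_amp = 0,
                   respiratory_amp = 0, vasomotor_amp = 0, drift_slope = 0,
                   noise_sd = 0, chromo_noise_sd = 0)
  sim <- simulate_fnirs(build_warble_protocol(), tr,
                        channel_labels = "S1-D1")
  ep2 <- epoch_blocks(sim$raw)
  expect_equal(min(ep2$epochs), -2, tolerance = 0.1)
  # epochs escaping the recording are dropped and logged
  ep3 <- epoch_blocks(sim$raw, onsets = c(30, 89))
  expect_equal(nrow(ep3$epochs), 1)
  expect_equal(ep3$n_dropped, 1)
})

test_that("grand average reports pointwise mean and SEM", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3))
  g <- grand_average(m)
  expect_equal(g$mean, c(1, 2, 3))
  expect_equal(g$sem, c(0, 0, 0))
  m2 <- rbind(c(2, -2), c(-2, 2))
  g2 <- grand_average(m2)
  expect_equal(g2$mean, c(0, 0))
  expect_equal(g2$sem, c(2, 2))
  expect_error(grand_average(m2[1, , drop = FALSE]), "at least 2")
})

test_that("PCA of epochs returns ordered orthogonal temporal components", {
  set.seed(7)
  shape <- sin(seq(0, pi, length.out = 50))
  weights <- stats::rnorm(20, mean = 3)
  rank1 <- outer(weights, shape)
  res <- pca_epochs(rank1)
  expect_equal(res$explained[1], 1, tolerance = 1e-9)
  expect_gt(abs(stats::cor(res$components[, 1], shape)), 1 - 1e-9)
  noisy <- rank1 + matrix(stats::rnorm(20 * 50, sd = 0.5), 20)
  res2 <- pca_epochs(noisy)
  expect_true(all(diff(res2$explained) <= 1e-12))
  expect_lte(sum(res2$explained), 1 + 1e-9)
  gram <- crossprod(res2$components[, 1:5])
  expect_equal(gram, diag(5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("task GLM recovers a noiseless amplitude exactly", {
  pr <- build_warble_protocol()
  fs <- 10
  n <- 920
  reg <- task_regressor(pr, fs, n)
  fit <- glm_task(matrix(2.0 * reg, 1), pr, sample_rate = fs)
  expect_equal(fit$channels$beta, 2.0, tolerance = 1e-9)
  expect_lt(fit$channels$p, 0.05)
  # adding an offset and drift changes nothing (they are modeled)
  tt <- (seq_len(n) - 1) / fs
  fit2 <- glm_task(matrix(2.0 * reg + 5 + 0.01 * tt, 1), pr,
                   sample_rate = fs)
  expect_equal(fit2$channels$beta, 2.0, tolerance = 1e-9)
  # a silence-only protocol gives a zero regressor: rank-deficient design
  silent <- pr
  silent$events <- silent$events[silent$events$kind == "silence", ]
  expect_error(glm_task(matrix(stats::rnorm(n), 1), silent,
                        sample_rate = fs), "rank-deficient")
})

test_that("GLM betas track heterogeneous channel amplitudes", {
  pr <- build_warble_protocol()
  tr <- hemo_truth(seed = 21)
  sim <- simulate_fnirs(pr, tr)
  fit <- glm_task(smooth_series(sim$raw), pr)
  expect_gt(stats::cor(fit$channels$beta, -tr$channel_betas), 0.95)
  # intensity decrease + negative-going kernel -> positive betas
  expect_true(all(fit$channels$beta > 0))
})

test_that("cross-correlation peaks at the right sign and lag", {
  pr <- build_warble_protocol()
  fs <- 10
  reg <- task_regressor(pr, fs, 920, negative = FALSE)
  cc <- crosscorr_task(matrix(reg, 1), reg, fs)
  expect_equal(cc$peak_r, 1)
  expect_equal(cc$lag_s, 0)
  cc2 <- crosscorr_task(matrix(-reg, 1), reg, fs)
  expect_equal(cc2$peak_r, -1)
  expect_equal(cc2$lag_s, 0)
  expect_error(crosscorr_task(matrix(reg, 1), reg[-1], fs), "same grid")
})

test_that("stimulation-vs-silence contrast matrices behave at the boundaries", {
  fs <- 10
  n <- 920
  # 2-s periodic signal with onsets on the period grid: every stimulation
  # segment equals every silence segment exactly
  per <- sin(2 * pi * (seq_len(n) - 1) / fs / 2)
  cm <- stim_silence_contrast(matrix(per, 1), onsets = c(30, 46, 62),
                              sample_rate = fs)
  expect_equal(dim(cm$r_matrix), c(3, 3))
  expect_true(all(abs(cm$r_matrix - 1) < 1e-9))
  expect_true(all(cm$p_matrix == 1))
  # injected response against flat silence: significant mean difference
  resp <- rep(0, n)
  resp[301:320] <- -5 + 0.01 * seq_len(20)  # depressed stimulation segment
  cm2 <- stim_silence_contrast(matrix(resp, 1), onsets = 30,
                               sample_rate = fs)
  expect_lt(cm2$p_matrix[1, 1], 0.05)
  expect_true(cm2$p_marks[1, 1])
  expect_error(stim_silence_contrast(matrix(per, 1), onsets = 0.5,
                                     sample_rate = fs), "escapes")
})

test_that("contrast p-value histogram has a bin edge exactly at 0.05", {
  set.seed(2)
  h <- p_histogram(stats::runif(500))
  expect_equal(sum(h$count), 500)
  expect_true(any(h$right == 0.05))
  expect_equal(nrow(h), 200)
})

test_that("spatial ANOVA has the repeated-measures degrees of freedom", {
  set.seed(11)
  b <- matrix(stats::rnorm(23 * 8), 23, 8)
  res <- spatial_anova(b)
  expect_equal(res$df_num, 7)
  expect_equal(res$df_den, 154)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # post-hoc matrix is symmetric with NA diagonal
  expect_true(all(is.na(diag(res$posthoc))))
  expect_equal(res$posthoc, t(res$posthoc))
  # cross-check F against a direct two-way decomposition
  S <- 23; C <- 8
  grand <- mean(b)
  ss_ch <- S * sum((colMeans(b) - grand)^2)
  ss_sub <- C * sum((rowMeans(b) - grand)^2)
  ss_tot <- sum((b - grand)^2)
  ss_err <- ss_tot - ss_ch - ss_sub
  f_manual <- (ss_ch / 7) / (ss_err / 154)
  expect_equal(res$F_value, f_manual, tolerance = 1e-9)
})

test_that("spatial ANOVA handles degenerate and invalid input", {
  # channels identical within each subject: F = 0, p = 1
  b <- matrix(rep(stats::rnorm(6), 4), nrow = 6)
  res <- spatial_anova(b, posthoc = FALSE)
  expect_equal(res$F_value, 0)
  expect_equal(res$p_value, 1)
  expect_error(spatial_anova(matrix(1, 1, 4)), "at least 2")
  expect_error(spatial_anova(matrix(1:6, 3, 2) * NA), "complete")
})

test_that("Holm correction matches the hand-computed step-down values", {
  expect_equal(holm_correct(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_correct(0.2), 0.2)
  set.seed(4)
  p <- stats::runif(20)
  expect_true(all(holm_correct(p) >= p))
  expect_error(holm_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH correction matches the hand-computed step-up values", {
  expect_equal(fdr_correct(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(fdr_correct(rep(0.03, 5)), rep(0.03, 5))
  set.seed(5)
  p <- stats::runif(20)
  expect_true(all(fdr_correct(p) >= p))
})

test_that("Holm and BH equal brute-force enumeration on all permutations", {
  base_p <- c(0.001, 0.008, 0.02, 0.04, 0.2, 0.7)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  for (k in c(1, 2, 3)) {
    for (pp in perms(base_p[seq_len(k + 2)])) {
      expect_equal(holm_correct(pp), oracle_holm(pp))
      expect_equal(fdr_correct(pp), oracle_bh(pp))
    }
  }
})
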