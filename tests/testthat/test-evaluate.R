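test_that("adjusted-Wald chance level reproduces the 54.3% bound at n = 360", {
  expect_equal(chance_level(360, 0.05), 54.3, tolerance = 0.05)
  expect_error(chance_level(360, 1.5), "alpha")
  expect_error(chance_level(0), "n_trials")
})

test_that("chance level decreases with trials and increases as alpha shrinks", {
  ns <- c(40, 100, 360, 1000, 10000)
  cl <- sapply(ns, chance_level)
  expect_true(all(diff(cl) < 0))
  expect_lt(chance_level(1e8), 50.01)          # large-n limit -> 50%
  expect_gt(chance_level(360, 0.01), chance_level(360, 0.05))
})

test_that("accuracy time-course summarises predictions against labels", {
  ses <- small_session(seed = 50, n_tpc = 6, erd_depth = 0.6)
  res <- run_session(ses$rec, policy = small_policy(first = 2, inc = 2))
  ac <- accuracy_timecourse(res)
  expect_true(all(ac$accuracy >= 0 & ac$accuracy <= 1))
  expect_gte(ac$peak, ac$mean)
  expect_equal(ac$n_trials, length(res$feedback_trials))
  # all-correct predictions give a flat curve at 1
  res2 <- res
  res2$preds[res$feedback_trials, ] <-
    matrix(res$labels[res$feedback_trials], length(res$feedback_trials),
           ncol(res$preds))
  ac2 <- accuracy_timecourse(res2)
  expect_equal(ac2$peak, 1)
  expect_equal(ac2$mean, 1)
  expect_true(all(ac2$accuracy == 1))
})

test_that("accuracy is invariant to trial order and random predictions sit at chance", {
  ses <- small_session(seed = 51, n_tpc = 6, erd_depth = 0.5)
  res <- run_session(ses$rec, policy = small_policy(first = 2, inc = 2))
  # order invariance: permute evaluated trials
  idx <- res$feedback_trials
  set.seed(1)
  perm <- sample(idx)
  expect_equal(accuracy_timecourse(res, trials = perm)$accuracy,
               accuracy_timecourse(res, trials = idx)$accuracy)
  # random predictions: simulate 360 coin-flip trials directly
  set.seed(2)
  res_rand <- res
  n_eval <- 360
  res_rand$preds <- matrix(sample(1:2, n_eval * ncol(res$preds), TRUE),
                           n_eval)
  res_rand$labels <- sample(rep(1:2, n_eval / 2))
  res_rand$feedback_trials <- seq_len(n_eval)
  ac <- accuracy_timecourse(res_rand)
  expect_lt(100 * ac$mean, chance_level(n_eval))
  expect_gt(100 * ac$mean, 100 - chance_level(n_eval))
})

test_that("stage-wise evaluation splits feedback trials per class ordinal", {
  ses <- small_session(seed = 52, n_tpc = 10, erd_depth = 0.5)
  res <- run_session(ses$rec, policy = small_policy(first = 2, inc = 2))
  tab <- stage_accuracy(res, stages = list(first = c(1, 4), second = c(5, 8)))
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$n_trials), length(res$feedback_trials))
  expect_equal(tab$n_trials[1], 8)             # both classes contribute 4
  expect_true(all(tab$peak_pct >= tab$mean_pct - 1e-9))
})

test_that("Laplacian derivation cancels common-mode signals", {
  fs <- 256
  common <- sin(2 * pi * 10 * seq_len(fs * 2) / fs) * 30
  sig <- matrix(rep(common, each = 13), 13)
  lap <- laplacian_derivation(sig)
  expect_lt(max(abs(lap)), 1e-10)
  expect_error(laplacian_derivation(sig[1:5, ], default_channels()[1:5]),
               "missing channel")
})

test_that("Welch PSD of white noise is flat at the theoretical level", {
  set.seed(53)
  fs <- 256
  x <- rnorm(fs * 120)
  wp <- coadaptBCI:::welch_psd(x, fs)
  sel <- wp$freq >= 5 & wp$freq <= 100
  # white noise with unit variance: two-sided density 1/fs, one-sided 2/fs
  expect_equal(mean(wp$psd[sel]), 2 / fs, tolerance = 0.05)
  expect_lt(stats::sd(wp$psd[sel]) / mean(wp$psd[sel]), 0.2)
})

test_that("chance level agrees with a Monte-Carlo coin-flip quantile", {
  set.seed(54)
  mc <- stats::rbinom(1e5, 360, 0.5) / 360
  q95 <- 100 * stats::quantile(mc, 0.95, names = FALSE)
  expect_lt(abs(chance_level(360, 0.05) - q95), 0.5)
})
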