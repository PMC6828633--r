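test_that("softmax maps scores to a proper probability vector", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  p <- softmax(c(1, 0))
  expect_equal(p, c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.7311, 0.2689))
  # overflow safety and saturation
  p_big <- softmax(c(1000, 0))
  expect_equal(p_big, c(1, 0))
  expect_true(all(is.finite(p_big)))
  # shift invariance, sums to 1
  z <- c(0.3, -1.2, 2.5)
  expect_equal(softmax(z + 17.5), softmax(z), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
  expect_true(all(softmax(z) > 0 & softmax(z) < 1))
  expect_error(softmax(c(1, NaN)), "finite")
})

test_that("peak class probability matches an exhaustive scan oracle", {
  set.seed(30)
  for (rep in 1:20) {
    s <- rnorm(25, sd = 2)
    got <- peak_class_probability(s)
    # brute-force scan over all samples x classes
    best <- 0; best_lab <- 1L
    for (i in seq_along(s)) {
      probs <- exp(c(0, s[i])) / sum(exp(c(0, s[i])))
      for (k in 1:2) if (probs[k] > best) { best <- probs[k]; best_lab <- k }
    }
    expect_equal(got$peak_prob, best, tolerance = 1e-12)
    expect_identical(got$label, best_lab)
  }
})

test_that("peak probability edge cases behave as documented", {
  z <- peak_class_probability(rep(0, 10))
  expect_equal(z$peak_prob, 0.5)
  expect_identical(z$label, 1L)               # tie -> class 1
  pos <- peak_class_probability(rep(5, 10))
  expect_identical(pos$label, 2L)
  expect_gt(pos$peak_prob, 0.99)
  expect_error(peak_class_probability(numeric(0)), "empty")
})

test_that("quartile gate keeps the middle band, inclusive at the borders", {
  p <- seq(0.51, 0.58, by = 0.01)             # 8 distinct, evenly spaced
  g <- quartile_gate(p)
  # direct sort-and-compare oracle
  q <- stats::quantile(p, c(0.25, 0.75), type = 7, names = FALSE)
  oracle_kept <- which(p >= q[1] & p <= q[2])
  expect_identical(g$kept, oracle_kept)
  expect_identical(sort(c(g$kept, g$discarded)), seq_along(p))
  expect_lt(length(g$kept), length(p))        # extremes discarded
  # identical confidences: Q1 = Q3 = value, all kept
  g_id <- quartile_gate(rep(0.7, 6))
  expect_identical(g_id$kept, 1:6)
  expect_length(g_id$discarded, 0)
  # fewer than 4 candidates: defer
  g3 <- quartile_gate(c(0.6, 0.7, 0.8))
  expect_true(g3$deferred)
  expect_length(g3$kept, 0)
})

test_that("supervised schedule: retrain count follows 1 + (n - first)/inc", {
  ses <- small_session(seed = 5, n_tpc = 9, erd_depth = 0.4)
  pol <- small_policy(first = 3, inc = 2)
  res <- run_session(ses$rec, policy = pol)
  lg <- retrain_log(res)
  expect_equal(lg$tpc[1], 3)                   # first training at first_tpc
  expect_equal(sum(lg$ok), 1 + (9 - 3) / 2)    # 4 model versions
  expect_equal(lg$tpc, c(3, 5, 7, 9))          # every 2 TPC of progress
  # feedback on every trial after the first model
  expect_equal(sum(res$n_feedback_per_class), 2 * 9 - lg$trial[1])
})

test_that("semi-supervised updates stay supervised through calibration", {
  ses <- small_session(seed = 6, n_tpc = 12, erd_depth = 0.6)
  pol <- retrain_policy("semisupervised", first_training_tpc = 3,
                        increment_tpc = 2, supervised_calibration_tpc = 6)
  res <- run_session(ses$rec, policy = pol)
  lg <- retrain_log(res)
  expect_true(all(lg$mode[lg$tpc <= 6] == "supervised"))
  semi_events <- lg[lg$mode == "semisupervised", ]
  expect_true(all(semi_events$tpc > 6))
})

test_that("no true label reaches a fit after the calibration switch", {
  ses <- small_session(seed = 7, n_tpc = 12, erd_depth = 0.6)
  pol <- retrain_policy("semisupervised", first_training_tpc = 3,
                        increment_tpc = 2, supervised_calibration_tpc = 6)
  res1 <- run_session(ses$rec, policy = pol)
  # flip the true labels of all post-calibration trials: models, scores and
  # the retrain log must be unchanged (only feedback correctness may move)
  labels2 <- ses$labels
  ord <- stats::ave(seq_along(labels2), labels2, FUN = seq_along)
  flip <- ord > 6
  labels2[flip] <- 3L - labels2[flip]
  res2 <- run_session(ses$rec, labels = labels2, policy = pol)
  expect_identical(res2$scores, res1$scores)
  expect_identical(res2$preds, res1$preds)
  expect_identical(retrain_log(res2)[c("trial", "mode", "n_used", "version")],
                   retrain_log(res1)[c("trial", "mode", "n_used", "version")])
})

test_that("model updates are atomic: one model version per trial", {
  ses <- small_session(seed = 8, n_tpc = 8, erd_depth = 0.5)
  res <- run_session(ses$rec, policy = small_policy(first = 3, inc = 2))
  lg <- retrain_log(res)
  v <- res$model_version
  expect_true(all(diff(v[v > 0]) >= 0))        # versions only move forward
  # a version change never happens at a trial that logged no event
  changes <- which(diff(v) > 0) + 1L
  expect_true(all((changes - 1L) %in% lg$trial[lg$ok]))
})

test_that("standalone retrain_step accumulates and emits models", {
  ses <- small_session(seed = 9, n_tpc = 4, erd_depth = 0.5)
  trials <- segment_trials(ses$rec)
  fb <- build_filterbank(fs = ses$rec$fs)
  pool <- training_pool(fb)
  pol <- small_policy(first = 2, inc = 1)
  model <- NULL
  versions <- integer(0)
  for (i in seq_along(trials)) {
    st <- retrain_step(pool, pol, trials[[i]], model = model)
    pool <- st$pool
    if (!is.null(st$model)) {
      model <- st$model
      versions <- c(versions, model$provenance$version)
    }
  }
  expect_gt(length(versions), 0)
  expect_identical(versions, seq_along(versions))
  expect_s3_class(model, "decoder_model")
})
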