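test_that("feedback bar shows only at >= 50% correct, boundary inclusive", {
  fb <- feedback_bar(c(rep(1L, 8), rep(2L, 8)), true_class = 1L)
  expect_equal(fb$fraction_correct, 0.5)
  expect_equal(fb$bar_length, 0.5)            # exactly 50% shows
  expect_equal(feedback_bar(rep(1L, 16), 1L)$bar_length, 1)
  fb7 <- feedback_bar(c(rep(1L, 7), rep(2L, 9)), 1L)
  expect_equal(fb7$fraction_correct, 7 / 16)
  expect_equal(fb7$bar_length, 0)             # below threshold: no bar
  expect_error(feedback_bar(integer(0), 1L), "no predictions")
})

test_that("bar length is never positive below 50% correct in a replay", {
  ses <- small_session(seed = 12, n_tpc = 6, erd_depth = 0.4)
  res <- run_session(ses$rec, policy = small_policy(first = 2, inc = 2))
  fb_rows <- res$feedback_trials
  frac <- res$frac_correct[fb_rows, ]
  bar <- res$bar_length[fb_rows, ]
  expect_true(all(bar[frac < 0.5] == 0))
  expect_true(all(bar[frac >= 0.5] == frac[frac >= 0.5]))
  expect_equal(res$feedback_times[1], res$timing$feedback_start_s)
})

test_that("the first trials produce no feedback and outputs come at 16 Hz", {
  ses <- small_session(seed = 13, n_tpc = 5, erd_depth = 0.5)
  res <- run_session(ses$rec, policy = small_policy(first = 2, inc = 2))
  pre <- which(res$model_version == 0L)
  expect_true(all(is.na(res$scores[pre, ])))
  expect_gte(length(pre), 4)                   # >= first_training_tpc trials
  expect_equal(res$times[1], 1)
  expect_equal(diff(res$times), rep(1 / 16, length(res$times) - 1))
  # 16 predictions per second of classifiable time
  expect_equal(sum(res$times > 4 & res$times <= 5), 16)
})

test_that("identical session and seed replay bit-identically", {
  ses <- small_session(seed = 14, n_tpc = 6, erd_depth = 0.4)
  pol <- small_policy(first = 2, inc = 2)
  r1 <- run_session(ses$rec, policy = pol, seed = 99)
  r2 <- run_session(ses$rec, policy = pol, seed = 99)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$preds, r2$preds)
  expect_identical(retrain_log(r1), retrain_log(r2))
  expect_identical(r1$final_model$slda$w, r2$final_model$slda$w)
})

test_that("no lookahead: truncating future trials leaves past outputs unchanged", {
  ses <- small_session(seed = 15, n_tpc = 6, erd_depth = 0.4)
  pol <- small_policy(first = 2, inc = 2)
  full <- run_session(ses$rec, policy = pol)
  # rebuild a recording containing only the first 8 trials
  keep <- 8L
  block <- diff(ses$rec$events$sample[1:2])
  cut <- ses$rec$events$sample[keep] + block
  rec_short <- eeg_recording(ses$rec$signal[, 1:cut],
                             ses$rec$fs, ses$rec$channel_labels,
                             ses$rec$events[1:keep, ])
  short <- run_session(rec_short, policy = pol)
  expect_identical(short$scores[1:keep, ], full$scores[1:keep, ])
  expect_identical(short$preds[1:keep, ], full$preds[1:keep, ])
})

test_that("run_comparison pairs both policies on the identical stream", {
  ses <- small_session(seed = 16, n_tpc = 10, erd_depth = 0.5)
  cmp <- run_comparison(
    ses$rec,
    supervised = small_policy("supervised", first = 3, inc = 2),
    semisupervised = retrain_policy("semisupervised", first_training_tpc = 3,
                                    increment_tpc = 2,
                                    supervised_calibration_tpc = 5))
  expect_s3_class(cmp$supervised, "session_result")
  expect_s3_class(cmp$semisupervised, "session_result")
  expect_identical(cmp$supervised$labels, cmp$semisupervised$labels)
  expect_equal(nrow(cmp$summary), 2)
  expect_lt(cmp$summary$retrainings[2], cmp$summary$retrainings[1])
})
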