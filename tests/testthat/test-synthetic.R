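test_that("identical config and seed give bit-identical sessions", {
  cfg <- synth_config(seed = 40, n_tpc = 3)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$rec$signal, s2$rec$signal)
  expect_identical(s1$labels, s2$labels)
})

test_that("class order is balanced within each run", {
  cfg <- synth_config(seed = 41, n_tpc = 20)
  ses <- generate_session(cfg)
  runs <- split(ses$labels, rep(seq_len(2), each = 20))
  for (r in runs) expect_equal(sum(r == 1L), sum(r == 2L))
})

test_that("erd_depth outside [0,1] is refused", {
  expect_error(synth_config(erd_depth = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(erd_depth = -0.1), "\\[0, 1\\]")
})

test_that("background noise has the configured power-law slope", {
  for (alpha in c(0.5, 1, 1.5)) {
    cfg <- synth_config(seed = 42, n_tpc = 4, noise_exponent = alpha,
                        osc_amp_mu = 0, osc_amp_beta = 0)
    ses <- generate_session(cfg)
    wp <- coadaptBCI:::welch_psd(ses$rec$signal[5, ], 256, seg_n = 512)
    sel <- wp$freq >= 2 & wp$freq <= 40
    fit <- stats::lm(log10(wp$psd[sel]) ~ log10(wp$freq[sel]))
    expect_equal(unname(stats::coef(fit)[2]), -alpha, tolerance = 0.3)
  }
})

test_that("hand imagery attenuates mu power at C3, feet at Cz", {
  cfg <- synth_config(seed = 43, n_tpc = 20, erd_depth = 0.6)
  ses <- generate_session(cfg)
  rep <- laplacian_psd(ses$rec)
  mu <- rep$freq >= 8 & rep$freq <= 12
  p <- function(ch, cond) mean(rep$psd[mu, ch, cond])
  # hand trials: mu dip at C3 relative to feet trials; feet dip at Cz
  expect_lt(p("C3", "hand"), p("C3", "feet"))
  expect_lt(p("Cz", "feet"), p("Cz", "hand"))
})

test_that("zero erd_depth leaves the classes statistically identical", {
  cfg <- synth_config(seed = 44, n_tpc = 20, erd_depth = 0)
  ses <- generate_session(cfg)
  rep <- laplacian_psd(ses$rec)
  mu <- rep$freq >= 8 & rep$freq <= 12
  diffC3 <- mean(rep$psd[mu, "C3", "hand"]) - mean(rep$psd[mu, "C3", "feet"])
  expect_lt(abs(diffC3), 0.5)     # dB; no systematic class difference
})

test_that("artifact injection is reproducible and inert at rate 0", {
  ses <- small_session(seed = 45, n_tpc = 5)
  none <- inject_artifacts(ses$rec, rate = 0, amp = 500, seed = 1)
  expect_identical(none$rec$signal, ses$rec$signal)
  expect_length(none$affected, 0)
  a1 <- inject_artifacts(ses$rec, rate = 0.4, amp = 500, seed = 7)
  a2 <- inject_artifacts(ses$rec, rate = 0.4, amp = 500, seed = 7)
  expect_identical(a1$affected, a2$affected)
  expect_identical(a1$rec$signal, a2$rec$signal)
  expect_error(inject_artifacts(ses$rec, rate = 2, amp = 500), "\\[0, 1\\]")
})

test_that("rate-1 500 uV artifacts trip the amplitude rejection in every trial", {
  ses <- small_session(seed = 46, n_tpc = 4)
  inj <- inject_artifacts(ses$rec, rate = 1, amp = 500, seed = 8)
  expect_length(inj$affected, 8)
  trials <- segment_trials(inj$rec)
  rep <- reject_outliers(trials)
  expect_true(all(rep$rejected))
  expect_true(all(rep$reason == "amplitude"))
})

test_that("stronger ERD does not decode worse on average (10 seeds)", {
  # lightweight end-to-end check: fixed split fit/test decoding accuracy
  acc_for <- function(seed, depth) {
    ses <- generate_session(synth_config(seed = seed, n_tpc = 10,
                                         erd_depth = depth))
    trials <- segment_trials(ses$rec)
    fb <- build_filterbank(fs = ses$rec$fs)
    train <- 1:10; test <- 11:20
    csp <- fit_csp_bank(trials[train], ses$labels[train], fb)
    feat <- function(idx) t(sapply(trials[idx], extract_features, csp = csp,
                                   fb = fb, at_time_s = 5.5))
    m <- fit_slda(feat(train), ses$labels[train])
    mean(predict(m, feat(test))$pred == ses$labels[test])
  }
  seeds <- 1:10
  lo <- mean(sapply(seeds, acc_for, depth = 0.1))
  hi <- mean(sapply(seeds, acc_for, depth = 0.7))
  expect_gte(hi, lo)
})
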