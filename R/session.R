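#' Feedback bar from trailing classifications
#'
#' The bar length equals the fraction of correct classifications within the
#' trailing 1-s window; if fewer than half are correct no bar is shown
#' (length 0), so users only ever see positive feedback. Exactly 50%
#' correct shows the bar.
#'
#' @param preds integer vector of predicted classes in the trailing 1-s
#'   window (must be non-empty).
#' @param true_class the cue's class code.
#' @return list with \code{fraction_correct} and \code{bar_length}.
#' @export
feedback_bar <- function(preds, true_class) {
  if (length(preds) < 1) stop("no predictions in trailing window")
  frac <- mean(preds == true_class)
  list(fraction_correct = frac,
       bar_length = if (frac >= 0.5) frac else 0)
}

#' Replay a full co-adaptive session
#'
#' Drives the online unit (stream classification at \code{rate_hz}) and a
#' recurrent training unit over a session, trial by trial, exactly as in a
#' closed-loop experiment: the first trials produce no feedback (no model
#' exists yet); once the first model is fitted, every subsequent trial is
#' scored at 16 outputs/s with the model installed at its start, the
#' feedback bar is computed from the trailing second of classifications
#' from 1.25 s after cue onset, and completed trials are handed to the
#' retraining unit, whose new models are installed at the next inter-trial
#' interval. Predictions never use future samples, and each trial is
#' decoded by exactly one model version.
#'
#' @param rec an \code{\link{eeg_recording}} with trial-start events coding
#'   the true classes.
#' @param labels optional integer labels per trial (default: event codes).
#' @param policy a \code{\link{retrain_policy}}.
#' @param config named list of decoder options: \code{fb} (filterbank),
#'   \code{timing}, \code{rate_hz} (16), \code{reject} (rejection
#'   parameters), \code{shrinkage} (CSP), \code{gamma} (sLDA).
#' @param seed stored in the result for provenance; the replay itself is
#'   deterministic.
#' @return An object of class \code{session_result}: per-trial score and
#'   prediction matrices (trials x output times, \code{NA} before the first
#'   model), feedback traces, model version per trial, the retrain-event
#'   log, labels, policy and seed.
#' @export
run_session <- function(rec, labels = NULL, policy = retrain_policy(),
                        config = list(), seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  timing <- config$timing %||% trial_timing()
  fb <- config$fb %||% build_filterbank(fs = rec$fs)
  rate_hz <- config$rate_hz %||% 16
  reject <- config$reject %||% list(amp_uv = 125, sd_mult = 4,
                                    band = c(3, 35), order = 8)
  trials <- segment_trials(rec, timing)
  n <- length(trials)
  if (is.null(labels)) labels <- vapply(trials, `[[`, integer(1), "true_label")

  pool <- training_pool(fb, timing, rec$fs, reject = reject,
                        shrinkage = config$shrinkage, gamma = config$gamma,
                        rate_hz = rate_hz)
  model <- NULL

  fs <- rec$fs
  step <- fs %/% rate_hz
  times <- seq.int(fs, round(timing$trial_len_s * fs), by = step) / fs
  n_t <- length(times)
  fb_sel <- times >= timing$feedback_start_s
  scores <- matrix(NA_real_, n, n_t)
  preds <- matrix(NA_integer_, n, n_t)
  frac_correct <- matrix(NA_real_, n, sum(fb_sel))
  bar_len <- matrix(NA_real_, n, sum(fb_sel))
  model_version <- integer(n)

  for (i in seq_len(n)) {
    band_signals <- apply_filterbank(fb, trials[[i]]$data, fs = fs)
    if (!is.null(model)) {
      ss <- classify_stream(trials[[i]]$data, model, rate_hz = rate_hz,
                            fs = fs, band_signals = band_signals)
      scores[i, ] <- ss$score
      preds[i, ] <- ss$pred
      model_version[i] <- model$provenance$version
      # feedback: fraction correct over the trailing second of outputs
      for (k in which(fb_sel)) {
        win <- which(times > times[k] - 1 & times <= times[k])
        fbv <- feedback_bar(preds[i, win], labels[i])
        kk <- k - which(fb_sel)[1] + 1L
        frac_correct[i, kk] <- fbv$fraction_correct
        bar_len[i, kk] <- fbv$bar_length
      }
    }
    st <- retrain_step(pool, policy, trials[[i]], model = model,
                       true_label = labels[i], band_signals = band_signals)
    pool <- st$pool
    if (!is.null(st$model)) model <- st$model   # installed before next trial
    if (i == n && is.null(model) && pool$version == 0L)
      stop("decoder could not be fitted on this session (no retrain event succeeded)")
  }

  fb_trials <- which(model_version > 0L)
  structure(list(times = times, feedback_times = times[fb_sel],
                 scores = scores, preds = preds,
                 frac_correct = frac_correct, bar_length = bar_len,
                 model_version = model_version,
                 events = pool$events, labels = labels,
                 policy = policy, seed = seed, fs = fs, timing = timing,
                 n_trials = n, feedback_trials = fb_trials,
                 n_feedback_per_class = c(sum(labels[fb_trials] == 1L),
                                          sum(labels[fb_trials] == 2L)),
                 final_model = model),
            class = "session_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_result <- function(x, ...) {
  ev <- retrain_log(x)
  cat(sprintf("<session_result> %d trials (%d/%d feedback per class), %d retrainings (%s)\n",
              x$n_trials, x$n_feedback_per_class[1], x$n_feedback_per_class[2],
              sum(ev$ok), x$policy$mode))
  invisible(x)
}

#' Replay both retraining policies on the same session
#'
#' Runs the supervised and the semi-supervised recurrent training unit over
#' an identical data stream (the between-policy comparison that motivates
#' the semi-supervised design) and returns the paired results with summary
#' accuracies and retrain counts.
#'
#' @param rec an \code{\link{eeg_recording}} with labelled events.
#' @param labels optional true labels per trial.
#' @param config decoder options, see \code{\link{run_session}}.
#' @param seed provenance seed passed to both replays.
#' @param supervised,semisupervised the two policies (defaults:
#'   \code{retrain_policy} in each mode).
#' @return list with \code{supervised} and \code{semisupervised}
#'   \code{session_result}s and a \code{summary} data.frame (policy,
#'   retrainings, peak and mean accuracy in percent).
#' @export
run_comparison <- function(rec, labels = NULL, config = list(), seed = NULL,
                           supervised = retrain_policy("supervised"),
                           semisupervised = retrain_policy("semisupervised")) {
  res_sup <- run_session(rec, labels, supervised, config, seed)
  res_semi <- run_session(rec, labels, semisupervised, config, seed)
  acc_sup <- accuracy_timecourse(res_sup)
  acc_semi <- accuracy_timecourse(res_semi)
  summary <- data.frame(
    policy = c("supervised", "semisupervised"),
    retrainings = c(sum(retrain_log(res_sup)$ok), sum(retrain_log(res_semi)$ok)),
    peak_acc_pct = 100 * c(acc_sup$peak, acc_semi$peak),
    mean_acc_pct = 100 * c(acc_sup$mean, acc_semi$mean))
  list(supervised = res_sup, semisupervised = res_semi, summary = summary)
}
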