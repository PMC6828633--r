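#' Softmax class probabilities
#'
#' Maps a vector of K linear scores to class probabilities by exponentiation
#' and normalization: \code{p_i = exp(z_i) / sum_j exp(z_j)}. Computed with
#' max subtraction, so arbitrarily large scores do not overflow; the result
#' is componentwise in (0,1), sums to 1, and is invariant to adding a
#' constant to all scores.
#'
#' @param z numeric vector of finite linear scores.
#' @return probability vector of the same length.
#' @export
softmax <- function(z) {
  if (!is.numeric(z) || length(z) < 1 || any(!is.finite(z)))
    stop("softmax requires a vector of finite scores")
  e <- exp(z - max(z))
  e / sum(e)
}

# two-class score s (positive = class 2) -> score vector (z1, z2) = (0, s)
binary_score_vector <- function(s) c(0, s)

#' Peak class probability of a trial
#'
#' For every feedback-period sample of a trial, the binary LDA linear score
#' is mapped through the softmax to class probabilities; per sample the
#' larger class probability is taken, and the trial's confidence is the
#' peak of these over the feedback period. The artificial label is the
#' class attaining that peak; a peak of exactly 0.5 (all scores zero) is
#' broken deterministically to class 1.
#'
#' @param scores numeric vector of linear scores over the feedback period,
#'   or a \code{score_series} from \code{\link{classify_stream}} (restricted
#'   to the feedback period by the caller).
#' @param classes integer class codes (score sign convention: positive =
#'   second element).
#' @return list with \code{peak_prob} and \code{label}.
#' @export
peak_class_probability <- function(scores, classes = bci_classes()) {
  if (inherits(scores, "score_series")) scores <- scores$score
  if (length(scores) < 1) stop("empty feedback period: no scores")
  if (any(!is.finite(scores))) stop("non-finite scores")
  p2 <- vapply(scores, function(s) softmax(binary_score_vector(s))[2], numeric(1))
  pmaxc <- pmax(p2, 1 - p2)
  i <- which.max(pmaxc)
  label <- if (p2[i] > 0.5) classes[[2]] else classes[[1]]
  list(peak_prob = pmaxc[i], label = as.integer(label))
}

#' Interquartile confidence gate
#'
#' Computes the first and third quartiles of the candidates' peak class
#' probabilities and keeps only candidates inside \code{[Q1, Q3]}
#' (inclusive): low-confidence trials sit near the decision boundary,
#' suspiciously high-confidence trials are likely outliers. With fewer than
#' 4 candidates the gate defers (nothing kept or discarded yet).
#'
#' @param peak_probs numeric vector of per-trial peak class probabilities.
#' @param bounds the quantile probabilities (default first and third
#'   quartile).
#' @param type quantile estimator type (see \code{\link[stats]{quantile}});
#'   default 7, linear interpolation between order statistics.
#' @return list with integer index vectors \code{kept} and
#'   \code{discarded}, the quartiles \code{q}, and \code{deferred}.
#' @export
quartile_gate <- function(peak_probs, bounds = c(0.25, 0.75), type = 7) {
  n <- length(peak_probs)
  if (n < 4)
    return(list(kept = integer(0), discarded = integer(0),
                q = c(NA_real_, NA_real_), deferred = TRUE))
  q <- stats::quantile(peak_probs, bounds, type = type, names = FALSE)
  keep <- peak_probs >= q[1] & peak_probs <= q[2]
  list(kept = which(keep), discarded = which(!keep), q = q, deferred = FALSE)
}

#' Retraining policy
#'
#' Schedule constants and mode of the recurrent training unit. Supervised
#' mode retrains with true labels whenever enough new trials per class have
#' survived outlier rejection (10 TPC for the first training, 5 new TPC
#' thereafter). Semi-supervised mode behaves identically for the first
#' \code{supervised_calibration_tpc} collected TPC; afterwards candidate
#' trials are labelled by the current decoder (softmax peak class
#' probability), passed through the interquartile confidence gate, and only
#' gate-surviving trials count toward the retraining quota and enter the
#' training pool -- with their artificial labels. Gate-discarded trials are
#' permanently dropped.
#'
#' @param mode \code{"supervised"} or \code{"semisupervised"}.
#' @param first_training_tpc trials per class required for the first model.
#' @param increment_tpc new surviving trials per class required per
#'   recurrent retraining.
#' @param supervised_calibration_tpc TPC trained with true labels before
#'   the semi-supervised switch (ignored in supervised mode).
#' @param quartile_bounds confidence-gate quantile bounds.
#' @param quartile_population \code{"batch"} (quartiles over the candidate
#'   batch accumulated since the last retraining; default) or \code{"pool"}
#'   (over all available scored trials).
#' @param label_rule \code{"peak"} (artificial label = class at the peak
#'   sample; default) or \code{"majority"} (majority vote over feedback
#'   samples, ties to class 1).
#' @return An object of class \code{retrain_policy}.
#' @export
retrain_policy <- function(mode = c("supervised", "semisupervised"),
                           first_training_tpc = 10, increment_tpc = 5,
                           supervised_calibration_tpc = 40,
                           quartile_bounds = c(0.25, 0.75),
                           quartile_population = c("batch", "pool"),
                           label_rule = c("peak", "majority")) {
  mode <- match.arg(mode)
  if (first_training_tpc < 1 || increment_tpc < 1)
    stop("first_training_tpc and increment_tpc must be >= 1")
  if (supervised_calibration_tpc < first_training_tpc)
    stop("calibration must cover at least the first training")
  structure(list(mode = mode, first_training_tpc = first_training_tpc,
                 increment_tpc = increment_tpc,
                 supervised_calibration_tpc = supervised_calibration_tpc,
                 quartile_bounds = quartile_bounds,
                 quartile_population = match.arg(quartile_population),
                 label_rule = match.arg(label_rule)),
            class = "retrain_policy")
}

#' Create an empty training pool
#'
#' The mutable state of a recurrent training unit: accumulated trials with
#' their cached band covariances and rejection-prefiltered copies, label
#' bookkeeping (true labels during calibration, artificial labels after the
#' semi-supervised switch), gating status, and the retrain-event log. Raw
#' trial data is not retained: everything a refit needs (CSP-epoch and
#' feature-window covariances per band, the 3-35 Hz copy for rejection) is
#' cached at entry.
#'
#' @param fb the \code{\link{build_filterbank}} shared with the online unit.
#' @param timing a \code{\link{trial_timing}}.
#' @param fs sampling rate, Hz.
#' @param reject named list of rejection parameters (\code{amp_uv},
#'   \code{sd_mult}, \code{band}, \code{order}).
#' @param shrinkage optional fixed CSP shrinkage; \code{NULL} = analytic.
#' @param gamma optional fixed sLDA shrinkage; \code{NULL} = analytic.
#' @param rate_hz score rate used when confidence-scoring candidates.
#' @return An object of class \code{training_pool}.
#' @export
training_pool <- function(fb, timing = trial_timing(), fs = fb$fs,
                          reject = list(amp_uv = 125, sd_mult = 4,
                                        band = c(3, 35), order = 8),
                          shrinkage = NULL, gamma = NULL, rate_hz = 16) {
  structure(list(fb = fb, timing = timing, fs = fs, reject = reject,
                 shrinkage = shrinkage, gamma = gamma, rate_hz = rate_hz,
                 entries = list(), class_arrivals = c(0L, 0L),
                 version = 0L, tpc_last = 0L, kept_tpc_last = 0L,
                 events = list()),
            class = "training_pool")
}

# cache everything a retrain will ever need from one trial
pool_prepare_entry <- function(pool, data, true_label, band_signals) {
  csp_covs <- lapply(band_signals, epoch_cov, timing = pool$timing, fs = pool$fs)
  tft <- pool$timing$lda_feature_time_s
  widx <- time_window_idx(tft - 1, tft, pool$fs)
  feat_covs <- lapply(band_signals, function(B) stats::cov(t(B[, widx, drop = FALSE])))
  filt <- bandpass_causal(data, pool$reject$band, pool$fs, pool$reject$order)
  list(true_label = as.integer(true_label),
       csp_covs = csp_covs, feat_covs = feat_covs, filt = filt,
       label_train = NA_integer_, label_source = NA_character_,
       status = "candidate",      # candidate | pooled | discarded
       era = NA_character_,       # calibration | post
       class_ordinal = NA_integer_,
       peak_prob = NA_real_, artificial_label = NA_integer_,
       rejected = FALSE)
}

# recompute rejection flags over all non-discarded entries
pool_run_rejection <- function(pool) {
  live <- which(vapply(pool$entries, function(e) e$status != "discarded", logical(1)))
  if (length(live) < 2) return(pool)
  filts <- lapply(pool$entries[live], `[[`, "filt")
  rep <- reject_from_filtered(filts, amp_uv = pool$reject$amp_uv,
                              sd_mult = pool$reject$sd_mult)
  for (k in seq_along(live))
    pool$entries[[live[k]]]$rejected <- rep$rejected[k]
  pool
}

# refit CSP bank + sLDA from cached covariances of the given entries;
# reads only label_train (the label firewall: no true label is touched
# here once entries carry artificial labels)
pool_refit <- function(pool, idx) {
  labels <- vapply(pool$entries[idx], `[[`, integer(1), "label_train")
  n_bands <- length(pool$fb$filters)
  cov_by_band <- lapply(seq_len(n_bands), function(bi)
    lapply(pool$entries[idx], function(e) e$csp_covs[[bi]]))
  csp <- fit_csp_bank_from_covs(cov_by_band, labels, pool$fb$band_names,
                                shrinkage = pool$shrinkage)
  feats <- t(vapply(pool$entries[idx], function(e)
    features_from_covs(e$feat_covs, csp),
    numeric(n_bands * length(csp$bands[[1]]$selected))))
  slda <- fit_slda(feats, labels, gamma = pool$gamma)
  src <- unique(vapply(pool$entries[idx], `[[`, character(1), "label_source"))
  decoder_model(pool$fb, csp, slda,
                provenance = list(version = pool$version + 1L,
                                  n_trials = length(idx),
                                  label_source = paste(sort(src), collapse = "+")))
}

pool_log_event <- function(pool, entry_id, tpc, mode, n_used, n_rejected,
                           n_gate_discarded, ok) {
  pool$events[[length(pool$events) + 1L]] <-
    data.frame(trial = entry_id, tpc = tpc, mode = mode, n_used = n_used,
               n_rejected = n_rejected, n_gate_discarded = n_gate_discarded,
               ok = ok, version = pool$version)
  pool
}

# entries eligible for training: not discarded, not currently rejected,
# carrying a training label
pool_training_idx <- function(pool) {
  which(vapply(pool$entries, function(e)
    e$status != "discarded" && !e$rejected && !is.na(e$label_train), logical(1)))
}

n_rejected_now <- function(pool)
  sum(vapply(pool$entries, function(e)
    e$status != "discarded" && e$rejected, logical(1)))

#' Advance a recurrent training unit by one completed trial
#'
#' Appends the trial to the pool and, when the policy's quota is met, runs
#' outlier rejection over all accumulated data, (in semi-supervised mode
#' after calibration) confidence-gates the candidate batch, and refits the
#' CSP bank and sLDA classifier on the eligible pool. The decoder in use is
#' never modified in place: a newly fitted model is returned for the caller
#' to install at the next inter-trial interval. If a refit fails on a
#' degenerate pool, the model is left unchanged and a failure event is
#' logged.
#'
#' @param pool a \code{\link{training_pool}}.
#' @param policy a \code{\link{retrain_policy}}.
#' @param trial a \code{\link{bci_trial}} or channels x samples matrix.
#' @param model the currently installed \code{\link{decoder_model}} (used
#'   to confidence-score post-calibration candidates; may be \code{NULL}
#'   before the first fit).
#' @param true_label class code of the cue (required if \code{trial} is a
#'   bare matrix).
#' @param band_signals optional precomputed filterbank output for the
#'   trial (the session driver passes the one it already computed).
#' @return list with \code{pool} (updated) and \code{model} (a new
#'   \code{decoder_model}, or \code{NULL} if no retraining occurred).
#' @export
retrain_step <- function(pool, policy, trial, model = NULL,
                         true_label = NULL, band_signals = NULL) {
  stopifnot(inherits(pool, "training_pool"), inherits(policy, "retrain_policy"))
  if (inherits(trial, "bci_trial")) {
    if (is.null(true_label)) true_label <- trial$true_label
    data <- trial$data
  } else data <- as.matrix(trial)
  if (is.null(true_label) || is.na(true_label))
    stop("true_label required (the cue class is known to the experimenter)")
  if (is.null(band_signals))
    band_signals <- apply_filterbank(pool$fb, data, fs = pool$fs)

  e <- pool_prepare_entry(pool, data, true_label, band_signals)
  cls <- if (true_label == 1L) 1L else 2L
  pool$class_arrivals[cls] <- pool$class_arrivals[cls] + 1L
  e$class_ordinal <- pool$class_arrivals[cls]
  calibration <- policy$mode == "supervised" ||
    e$class_ordinal <= policy$supervised_calibration_tpc
  e$era <- if (calibration) "calibration" else "post"
  if (calibration) {
    e$label_train <- as.integer(true_label)
    e$label_source <- "true"
  }
  pool$entries[[length(pool$entries) + 1L]] <- e
  id <- length(pool$entries)
  tpc <- min(pool$class_arrivals)

  if (e$era == "post" && !is.null(model)) {
    ss <- classify_stream(data, model, rate_hz = pool$rate_hz, fs = pool$fs,
                          band_signals = band_signals)
    fbsel <- ss$time >= pool$timing$feedback_start_s
    pool <- pool_score_candidate(pool, id, ss$score[fbsel], policy)
  }

  if (e$era == "calibration")
    supervised_trigger(pool, policy, id, tpc)
  else
    semisupervised_trigger(pool, policy, id, tpc)
}

# ---- supervised (and calibration-era) trigger ------------------------------

# Progress is counted in cumulative surviving TPC, min over the two classes:
# a retraining fires when that count has grown by the policy's increment
# since the last successful retraining (10 TPC for the very first). Counting
# the class minimum means a temporary surplus of one class is never lost to
# a counter reset.
min_tpc <- function(labels) min(sum(labels == 1L), sum(labels == 2L))

supervised_trigger <- function(pool, policy, id, tpc) {
  needed <- if (pool$version == 0L) policy$first_training_tpc else policy$increment_tpc
  live <- which(vapply(pool$entries, function(e)
    e$status != "discarded" && identical(e$era, "calibration"), logical(1)))
  raw <- min_tpc(vapply(pool$entries[live], `[[`, integer(1), "true_label"))
  if (raw < pool$tpc_last + needed)
    return(list(pool = pool, model = NULL))
  pool <- pool_run_rejection(pool)
  surv <- live[!vapply(pool$entries[live], `[[`, logical(1), "rejected")]
  cur <- min_tpc(vapply(pool$entries[surv], `[[`, integer(1), "true_label"))
  if (cur < pool$tpc_last + needed)
    return(list(pool = pool, model = NULL))
  train_idx <- pool_training_idx(pool)
  res <- tryCatch(pool_refit(pool, train_idx), error = function(err) err)
  ok <- !inherits(res, "error")
  if (ok) {
    pool$version <- pool$version + 1L
    pool$tpc_last <- cur
  }
  pool <- pool_log_event(pool, id, tpc, "supervised", length(train_idx),
                         n_rejected_now(pool), 0L, ok)
  list(pool = pool, model = if (ok) res else NULL)
}

# ---- semi-supervised trigger ----------------------------------------------

semisupervised_trigger <- function(pool, policy, id, tpc) {
  needed <- policy$increment_tpc
  batch_of <- function(p) which(vapply(p$entries, function(e)
    identical(e$era, "post") && e$status == "candidate" &&
      !is.na(e$artificial_label), logical(1)))
  batch <- batch_of(pool)
  alab <- vapply(pool$entries[batch], `[[`, integer(1), "artificial_label")
  if (min_tpc(alab) < needed || length(batch) < 4)
    return(list(pool = pool, model = NULL))
  pool <- pool_run_rejection(pool)
  batch <- batch[!vapply(pool$entries[batch], `[[`, logical(1), "rejected")]
  alab <- vapply(pool$entries[batch], `[[`, integer(1), "artificial_label")
  if (min_tpc(alab) < needed || length(batch) < 4)
    return(list(pool = pool, model = NULL))

  probs <- vapply(pool$entries[batch], `[[`, numeric(1), "peak_prob")
  gate_pop <- if (policy$quartile_population == "pool") {
    scored <- which(vapply(pool$entries, function(e)
      e$status != "discarded" && !is.na(e$peak_prob), logical(1)))
    vapply(pool$entries[scored], `[[`, numeric(1), "peak_prob")
  } else probs
  q <- stats::quantile(gate_pop, policy$quartile_bounds, type = 7, names = FALSE)
  keep <- probs >= q[1] & probs <= q[2]
  for (k in which(keep)) {
    i <- batch[k]
    pool$entries[[i]]$status <- "pooled"
    pool$entries[[i]]$label_train <- pool$entries[[i]]$artificial_label
    pool$entries[[i]]$label_source <- "artificial"
  }
  for (k in which(!keep)) pool$entries[[batch[k]]]$status <- "discarded"
  n_disc <- sum(!keep)

  # quota over gate survivors, again in cumulative per-class (min) counts
  kept <- which(vapply(pool$entries, function(e)
    identical(e$era, "post") && e$status == "pooled" && !e$rejected, logical(1)))
  kept_tpc <- min_tpc(vapply(pool$entries[kept], `[[`, integer(1), "label_train"))
  if (kept_tpc < pool$kept_tpc_last + needed) {
    # quota not yet met by gate survivors: no retraining this time
    return(list(pool = pool, model = NULL))
  }
  train_idx <- pool_training_idx(pool)
  res <- tryCatch(pool_refit(pool, train_idx), error = function(err) err)
  ok <- !inherits(res, "error")
  if (ok) {
    pool$version <- pool$version + 1L
    pool$kept_tpc_last <- kept_tpc
  }
  pool <- pool_log_event(pool, id, tpc, "semisupervised", length(train_idx),
                         n_rejected_now(pool), n_disc, ok)
  list(pool = pool, model = if (ok) res else NULL)
}

#' Attach decoder confidence to a pool entry
#'
#' Stores a candidate trial's peak class probability and artificial label
#' (computed from its feedback-period linear scores under the decoder that
#' was installed when it arrived). Called by \code{\link{retrain_step}};
#' exposed for building custom drivers.
#'
#' @param pool a \code{\link{training_pool}}.
#' @param id entry index.
#' @param scores linear scores over the trial's feedback period.
#' @param policy the \code{\link{retrain_policy}} (for the label rule).
#' @return the updated pool.
#' @export
pool_score_candidate <- function(pool, id, scores, policy) {
  pk <- peak_class_probability(scores)
  lab <- pk$label
  if (policy$label_rule == "majority") {
    if (inherits(scores, "score_series")) scores <- scores$score
    votes2 <- sum(scores > 0)
    lab <- if (votes2 * 2 > length(scores)) 2L else 1L
  }
  pool$entries[[id]]$peak_prob <- pk$peak_prob
  pool$entries[[id]]$artificial_label <- lab
  pool
}

#' Retrain-event log as a data.frame
#'
#' @param x a \code{\link{training_pool}} or a \code{session_result}.
#' @return data.frame with one row per retrain event: trial index, TPC
#'   count, mode, trials used, rejected count, gate-discarded count,
#'   success flag, resulting model version.
#' @export
retrain_log <- function(x) {
  events <- x$events
  if (!length(events))
    return(data.frame(trial = integer(), tpc = integer(), mode = character(),
                      n_used = integer(), n_rejected = integer(),
                      n_gate_discarded = integer(), ok = logical(),
                      version = integer()))
  do.call(rbind, events)
}
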