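# per-channel excess-free kurtosis m4/m2^2, averaged over channels
trial_kurtosis <- function(X) {
  ctr <- X - rowMeans(X)
  m2 <- rowMeans(ctr^2)
  m4 <- rowMeans(ctr^4)
  k <- ifelse(m2 > 0, m4 / m2^2, 0)
  mean(k)
}

# EEGLAB-style joint probability: per channel, empirical histogram density
# of the pooled samples; per trial the mean negative log-density of its own
# samples, averaged over channels. filts: list of channels x samples
# matrices (all same dims). Returns one score per trial.
jointprob_scores <- function(filts, nbins = 200) {
  n_trials <- length(filts)
  n_ch <- nrow(filts[[1]])
  ns <- ncol(filts[[1]])
  scores <- matrix(0, n_trials, n_ch)
  for (c in seq_len(n_ch)) {
    pooled <- unlist(lapply(filts, function(X) X[c, ]), use.names = FALSE)
    rng <- range(pooled)
    if (rng[1] == rng[2]) next                     # constant channel: score 0
    edges <- seq(rng[1], rng[2], length.out = nbins + 1)
    idx <- findInterval(pooled, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    p <- tabulate(idx, nbins) / length(pooled)
    nll <- -log(p[idx])
    dim(nll) <- c(ns, n_trials)
    scores[, c] <- colMeans(nll)
  }
  rowMeans(scores)
}

# core rejection over pre-filtered (3-35 Hz) trials
reject_from_filtered <- function(filts, amp_uv = 125, sd_mult = 4) {
  n <- length(filts)
  max_amp <- vapply(filts, function(X) max(abs(X)), numeric(1))
  kurt <- vapply(filts, trial_kurtosis, numeric(1))
  jp <- jointprob_scores(filts)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_jp <- zscore(jp)
  z_k <- zscore(kurt)
  f_amp <- max_amp > amp_uv
  f_jp <- z_jp > sd_mult            # one-sided: only abnormally improbable
  f_k <- abs(z_k) > sd_mult         # two-sided
  reason <- rep(NA_character_, n)
  reason[f_k] <- "kurtosis"
  reason[f_jp] <- "jointprob"
  reason[f_amp] <- "amplitude"
  data.frame(trial = seq_len(n), max_amp_uv = max_amp,
             jointprob = jp, kurtosis = kurt,
             z_jointprob = z_jp, z_kurtosis = z_k,
             rejected = f_amp | f_jp | f_k, reason = reason)
}

#' Statistical outlier rejection of trials
#'
#' Implements the pre-retraining trial rejection: a 3-35 Hz bandpass copy of
#' every trial is screened with three rules -- (1) any sample exceeding
#' +/- 125 microvolts, (2) abnormal joint probability (per-channel empirical
#' negative log-likelihood of the trial's samples under the amplitude
#' distribution pooled over all trials, averaged over channels), (3)
#' abnormal kurtosis (per-channel sample kurtosis averaged over channels).
#' For the latter two a trial is flagged when its statistic deviates more
#' than \code{sd_mult} standard deviations from the trial-population mean
#' (one-sided high for joint probability, two-sided for kurtosis; a
#' zero-variance population flags nothing). The filtered copy is used only
#' for screening -- the original data is what enters training.
#'
#' @param trials list of \code{\link{bci_trial}} objects or channels x
#'   samples matrices.
#' @param fs sampling rate, Hz (taken from the trials if they carry one).
#' @param amp_uv amplitude threshold, microvolts.
#' @param sd_mult SD multiple for the joint-probability and kurtosis rules.
#' @param band rejection prefilter passband, Hz.
#' @param order prefilter order (overall bandpass order).
#' @return An object of class \code{rejection_report}: a data.frame with one
#'   row per trial (statistics, z-scores, \code{rejected} flag and
#'   \code{reason}, one of \code{"amplitude"}, \code{"jointprob"},
#'   \code{"kurtosis"}), with the thresholds in attributes.
#' @export
reject_outliers <- function(trials, fs = NULL, amp_uv = 125, sd_mult = 4,
                            band = c(3, 35), order = 8) {
  if (length(trials) < 2)
    stop("outlier rejection needs at least 2 trials (SD thresholds require a population)")
  mats <- lapply(trials, function(tr) if (inherits(tr, "bci_trial")) tr$data else as.matrix(tr))
  if (is.null(fs)) {
    fs <- if (inherits(trials[[1]], "bci_trial")) trials[[1]]$fs else
      stop("fs must be given for bare matrices")
  }
  filts <- lapply(mats, bandpass_causal, band = band, fs = fs, order = order)
  rep <- reject_from_filtered(filts, amp_uv = amp_uv, sd_mult = sd_mult)
  attr(rep, "thresholds") <- list(amp_uv = amp_uv, sd_mult = sd_mult,
                                  band = band, order = order)
  class(rep) <- c("rejection_report", class(rep))
  rep
}
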