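#' Accuracy time-course of a replayed session
#'
#' Per output timepoint, the fraction of evaluated feedback trials whose
#' hard prediction matches the cue class; the peak accuracy is the maximum
#' over timepoints and the mean accuracy is averaged over the half-open
#' evaluation window (default seconds 4-8 from trial start, i.e. seconds
#' 1-5 after cue onset).
#'
#' @param result a \code{session_result} from \code{\link{run_session}}.
#' @param true_labels labels to score against (default: the session's).
#' @param trials optional subset of trial indices to evaluate (intersected
#'   with the feedback trials).
#' @return An object of class \code{accuracy_timecourse}: list with
#'   \code{time}, \code{accuracy}, \code{peak}, \code{mean},
#'   \code{n_trials}.
#' @export
accuracy_timecourse <- function(result, true_labels = result$labels,
                                trials = NULL) {
  stopifnot(inherits(result, "session_result"))
  idx <- result$feedback_trials
  if (!is.null(trials)) idx <- intersect(idx, trials)
  if (!length(idx)) stop("no feedback trials to evaluate")
  correct <- result$preds[idx, , drop = FALSE] == true_labels[idx]
  acc <- colMeans(correct)
  win <- result$timing$eval_window
  in_win <- result$times >= win[1] & result$times < win[2]
  structure(list(time = result$times, accuracy = acc,
                 peak = max(acc), mean = mean(acc[in_win]),
                 n_trials = length(idx)),
            class = "accuracy_timecourse")
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  cat(sprintf("<accuracy_timecourse> %d trials: peak %.1f%%, mean %.1f%% over evaluation window\n",
              x$n_trials, 100 * x$peak, 100 * x$mean))
  invisible(x)
}

#' Stage-wise accuracy table
#'
#' Splits the feedback trials into experiment stages by their per-class
#' feedback ordinal (default: the calibration stage and the three
#' between-break evaluation stages) and reports peak and mean accuracy per
#' stage.
#'
#' @param result a \code{session_result}.
#' @param stages named list of inclusive per-class feedback-trial ranges.
#' @return data.frame with columns \code{stage}, \code{peak_pct},
#'   \code{mean_pct}, \code{n_trials}.
#' @export
stage_accuracy <- function(result,
                           stages = list("Initial" = c(1, 40),
                                         "Eval 1" = c(41, 90),
                                         "Eval 2" = c(91, 140),
                                         "Eval 3" = c(141, 180))) {
  idx <- result$feedback_trials
  lab <- result$labels[idx]
  ord <- stats::ave(seq_along(idx), lab, FUN = seq_along)
  rows <- lapply(names(stages), function(nm) {
    r <- stages[[nm]]
    sel <- idx[ord >= r[1] & ord <= r[2]]
    if (!length(sel)) return(NULL)
    ac <- accuracy_timecourse(result, trials = sel)
    data.frame(stage = nm, peak_pct = 100 * ac$peak, mean_pct = 100 * ac$mean,
               n_trials = ac$n_trials)
  })
  do.call(rbind, rows)
}

#' Chance-level accuracy from the adjusted Wald interval
#'
#' Upper limit of the adjusted Wald (Agresti-Coull with two pseudo
#' successes and failures) confidence interval for a binomial proportion at
#' p = 0.5: with x = n/2, p~ = (x+2)/(n+4) and the bound is
#' p~ + z(1-alpha) sqrt(p~ (1-p~) / (n+4)), in percent. The one-sided
#' 1-alpha quantile is used with n the total number of evaluated trials
#' (both classes pooled); accuracies above this bound are better than
#' chance. For 360 trials at alpha = 0.05 the bound is 54.3%.
#'
#' @param n_trials number of evaluated trials.
#' @param alpha significance level in (0, 1).
#' @return chance-level accuracy in percent.
#' @export
chance_level <- function(n_trials, alpha = 0.05) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  p_adj <- (n_trials / 2 + 2) / (n_trials + 4)
  bound <- p_adj + stats::qnorm(1 - alpha) * sqrt(p_adj * (1 - p_adj) / (n_trials + 4))
  100 * bound
}

#' Small-Laplacian derivation
#'
#' Re-references each requested channel by subtracting the mean of its four
#' orthogonal neighbours (C3 from C1/C5/FC3/CP3, Cz from C1/C2/FCz/CPz, C4
#' from C2/C6/FC4/CP4), sharpening spatial focality.
#'
#' @param signal channels x samples matrix.
#' @param channel_labels labels for the rows of \code{signal}.
#' @param channels channels to derive.
#' @return matrix (length(channels) x samples) of Laplacian signals.
#' @export
laplacian_derivation <- function(signal, channel_labels = default_channels(),
                                 channels = c("C3", "Cz", "C4")) {
  nb <- laplacian_neighbours()
  out <- matrix(0, length(channels), ncol(signal),
                dimnames = list(channels, NULL))
  for (ch in channels) {
    if (!ch %in% names(nb)) stop("no Laplacian neighbour set for channel ", ch)
    need <- c(ch, nb[[ch]])
    missing <- setdiff(need, channel_labels)
    if (length(missing))
      stop("missing channel(s) for Laplacian derivation of ", ch, ": ",
           paste(missing, collapse = ", "))
    ci <- match(ch, channel_labels)
    ni <- match(nb[[ch]], channel_labels)
    out[ch, ] <- signal[ci, ] - colMeans(signal[ni, , drop = FALSE])
  }
  out
}

# Welch PSD of one vector: non-overlapping Hann-windowed segments of
# seg_n samples, averaged modified periodograms, density scaling (power
# per Hz). Returns freq (0..fs/2) and psd.
welch_psd <- function(x, fs, seg_n = fs) {
  n_seg <- floor(length(x) / seg_n)
  if (n_seg < 1) stop("signal shorter than one Welch segment")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_n) / (seg_n + 1)))
  scale <- fs * sum(w^2)
  n_f <- floor(seg_n / 2) + 1
  acc <- numeric(n_f)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * seg_n + 1):(s * seg_n)]
    X <- stats::fft((seg - mean(seg)) * w)
    pxx <- Mod(X[seq_len(n_f)])^2 / scale
    pxx[2:(n_f - 1)] <- 2 * pxx[2:(n_f - 1)]
    acc <- acc + pxx
  }
  list(freq = (seq_len(n_f) - 1) * fs / seg_n, psd = acc / n_seg)
}

#' Condition-averaged Laplacian Welch power spectra
#'
#' For each derived channel (C3, Cz, C4) and condition, estimates the power
#' spectral density with Welch's method (1-s segments, no overlap) over the
#' feedback period of every trial and averages over the condition's trials.
#' Reported in dB.
#'
#' @param rec an \code{\link{eeg_recording}} with labelled trial events.
#' @param timing a \code{\link{trial_timing}} (supplies the feedback
#'   period: feedback start to trial end).
#' @param channels channels to derive.
#' @param labels optional labels per trial (default: event codes).
#' @return An object of class \code{psd_report}: list with \code{freq} and
#'   \code{psd}, an array (frequency x channel x condition) in dB.
#' @export
laplacian_psd <- function(rec, timing = trial_timing(),
                          channels = c("C3", "Cz", "C4"), labels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  lap <- laplacian_derivation(rec$signal, rec$channel_labels, channels)
  trials <- segment_trials(eeg_recording(lap, rec$fs, channels, rec$events),
                           timing)
  if (is.null(labels)) labels <- vapply(trials, `[[`, integer(1), "true_label")
  conds <- sort(unique(labels))
  fs <- rec$fs
  widx <- time_window_idx(timing$feedback_start_s, timing$trial_len_s, fs)
  n_f <- floor(fs / 2) + 1
  psd <- array(0, dim = c(n_f, length(channels), length(conds)),
               dimnames = list(NULL, channels,
                               names(bci_classes())[match(conds, bci_classes())]))
  freq <- NULL
  for (ci in seq_along(conds)) {
    sel <- which(labels == conds[ci])
    for (chi in seq_along(channels)) {
      acc <- numeric(n_f)
      for (ti in sel) {
        wp <- welch_psd(trials[[ti]]$data[chi, widx], fs, seg_n = fs)
        acc <- acc + wp$psd
        freq <- wp$freq
      }
      psd[, chi, ci] <- acc / length(sel)
    }
  }
  structure(list(freq = freq, psd = 10 * log10(pmax(psd, 1e-20)),
                 params = list(seg_s = 1, overlap = 0, window = "hann",
                               period = c(timing$feedback_start_s,
                                          timing$trial_len_s))),
            class = "psd_report")
}
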