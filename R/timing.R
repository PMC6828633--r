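#' Trial timing landmarks
#'
#' Timing conventions for one motor-imagery trial, in seconds relative to
#' trial start (fixation-cross onset = 0 s). The cue appears at 3 s, the
#' imagery period spans 3-8 s, the feedback bar appears 1.25 s into the
#' imagery period, CSP filters are trained on the 4.75-7.75 s epoch, LDA
#' features are taken at 5.5 s, and accuracies are summarised over seconds
#' 4-8. All windows are half-open \code{[start, end)} with 0-based sample
#' indexing, so a 1-s window holds exactly \code{fs} samples.
#'
#' @param trial_len_s trial length in seconds.
#' @param cue_onset_s time of the class cue.
#' @param imagery_start_s,imagery_end_s imagery period bounds.
#' @param feedback_start_s first time at which the feedback bar may be shown
#'   (cue onset + 1.25 s).
#' @param csp_epoch length-2 numeric, half-open epoch used for CSP training.
#' @param lda_feature_time_s time at which the training feature vector is
#'   extracted (the window is the preceding second).
#' @param eval_window length-2 numeric, half-open window over which mean
#'   accuracy is computed.
#' @return An object of class \code{trial_timing}.
#' @export
trial_timing <- function(trial_len_s = 8, cue_onset_s = 3,
                         imagery_start_s = 3, imagery_end_s = 8,
                         feedback_start_s = 4.25,
                         csp_epoch = c(4.75, 7.75),
                         lda_feature_time_s = 5.5,
                         eval_window = c(4, 8)) {
  tm <- list(trial_len_s = trial_len_s, cue_onset_s = cue_onset_s,
             imagery_start_s = imagery_start_s, imagery_end_s = imagery_end_s,
             feedback_start_s = feedback_start_s, csp_epoch = csp_epoch,
             lda_feature_time_s = lda_feature_time_s, eval_window = eval_window)
  marks <- c(cue_onset_s, imagery_start_s, imagery_end_s, feedback_start_s,
             csp_epoch, lda_feature_time_s, eval_window)
  if (any(marks < 0) || any(marks > trial_len_s))
    stop("all timing landmarks must lie within [0, trial_len_s]")
  if (csp_epoch[2] <= csp_epoch[1])
    stop("csp_epoch must be an increasing interval")
  structure(tm, class = "trial_timing")
}

#' Session structure
#'
#' Describes the trial-count structure of a session: trials per class (TPC),
#' run grouping and break positions. The default mirrors a 190-TPC session
#' recorded in 19 runs of 10 TPC with extended breaks after 40, 90 and 140
#' TPC.
#'
#' @param n_tpc trials per class.
#' @param n_classes number of classes (fixed at 2).
#' @param run_tpc trials per class within one run.
#' @param break_positions TPC counts after which an extended break occurs.
#' @param inter_trial_interval_s pause between consecutive trials, seconds.
#'   Not prescribed by the paradigm description; configurable.
#' @return An object of class \code{session_spec}.
#' @export
session_spec <- function(n_tpc = 190, n_classes = 2, run_tpc = 10,
                         break_positions = c(40, 90, 140),
                         inter_trial_interval_s = 2) {
  if (n_classes != 2) stop("only two-class sessions are supported")
  if (n_tpc < 1 || run_tpc < 1) stop("n_tpc and run_tpc must be >= 1")
  if (length(break_positions) &&
      (is.unsorted(break_positions, strictly = TRUE) ||
       any(break_positions >= n_tpc)))
    stop("break positions must be strictly increasing and < n_tpc")
  structure(list(n_tpc = n_tpc, n_classes = n_classes, run_tpc = run_tpc,
                 break_positions = break_positions,
                 inter_trial_interval_s = inter_trial_interval_s),
            class = "session_spec")
}

# sample index range (1-based, for matrix columns) of half-open [t0, t1) s
time_window_idx <- function(t0, t1, fs) {
  i0 <- round(t0 * fs)
  i1 <- round(t1 * fs)
  if (i1 <= i0) stop("empty time window")
  seq.int(i0 + 1L, i1)
}

#' Class labels
#'
#' Integer class codes used throughout: 1 = right-hand motor imagery
#' ("hand"), 2 = both-feet motor imagery ("feet").
#' @export
bci_classes <- function() c(hand = 1L, feet = 2L)
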