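#' Default motor-cortex montage
#'
#' The 13 electrode positions over sensorimotor cortex used by the decoding
#' chain, in canonical order.
#' @export
default_channels <- function() {
  c("FC3", "FCz", "FC4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CPz", "CP4")
}

#' Continuous EEG recording
#'
#' Container for a continuous multichannel EEG signal with event markers.
#' Signals are stored channels x samples in microvolts. Event sample indices
#' are 0-based (sample 0 is the first sample), consistent with the half-open
#' window convention used everywhere else.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of
#'   \code{signal}.
#' @param events data.frame with columns \code{sample} (0-based index of the
#'   trial start) and \code{code} (integer class code, see
#'   \code{\link{bci_classes}}).
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(signal, fs = 256, channel_labels = default_channels(),
                          events = data.frame(sample = integer(), code = integer())) {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (nrow(signal) != length(channel_labels))
    stop("channel count (", nrow(signal), ") must equal label count (",
         length(channel_labels), ")")
  if (anyNA(signal)) stop("signal contains NaN/NA values")
  if (!all(c("sample", "code") %in% names(events)))
    stop("events must have columns 'sample' and 'code'")
  if (nrow(events) && (any(events$sample < 0) || any(events$sample >= ncol(signal))))
    stop("event sample indices must lie strictly within the signal")
  structure(list(signal = signal, fs = fs,
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

#' One segmented trial
#'
#' @param data channels x samples matrix covering one full trial from trial
#'   start.
#' @param fs sampling rate in Hz.
#' @param true_label integer class code, or \code{NA} if unknown.
#' @param artificial_label decoder-assigned class code (semi-supervised
#'   mode), or \code{NA}.
#' @return An object of class \code{bci_trial}.
#' @export
bci_trial <- function(data, fs, true_label = NA_integer_,
                      artificial_label = NA_integer_) {
  structure(list(data = data, fs = fs,
                 true_label = true_label,
                 artificial_label = artificial_label,
                 rejected = FALSE, reject_reason = NA_character_,
                 peak_class_prob = NA_real_),
            class = "bci_trial")
}

#' Segment a continuous recording into trials
#'
#' Cuts one fixed-length epoch per event marker, starting at the event
#' sample (trial start = fixation-cross onset). Trials are returned in
#' temporal order.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param timing a \code{\link{trial_timing}}.
#' @return list of \code{\link{bci_trial}} objects; the event code is stored
#'   as the trial's \code{true_label}.
#' @export
segment_trials <- function(rec, timing = trial_timing()) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(timing$trial_len_s * rec$fs)
  ev <- rec$events[order(rec$events$sample), , drop = FALSE]
  n_samp <- ncol(rec$signal)
  lapply(seq_len(nrow(ev)), function(i) {
    s0 <- ev$sample[i]
    if (s0 + len > n_samp)
      stop(sprintf("event %d at sample %d leaves only %d of %d required samples",
                   i, s0, n_samp - s0, len))
    bci_trial(rec$signal[, (s0 + 1L):(s0 + len), drop = FALSE], rec$fs,
              true_label = as.integer(ev$code[i]))
  })
}

SESSION_FORMAT <- "coadaptBCI-session"
SESSION_VERSION <- 1L

#' Save / load a session container
#'
#' Persists an \code{eeg_recording} together with optional labels and a
#' \code{session_result} in a single-file container (R serialization with a
#' format header). Loading reproduces the signal bit-exactly and all
#' metadata fields exactly.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param path file path.
#' @param labels optional integer vector of true labels per trial.
#' @param result optional \code{session_result}.
#' @param meta optional named list of extra metadata.
#' @return \code{save_session} returns \code{path} invisibly;
#'   \code{load_session} returns a list with elements \code{rec},
#'   \code{labels}, \code{result}, \code{meta}.
#' @export
save_session <- function(rec, path, labels = NULL, result = NULL, meta = list()) {
  stopifnot(inherits(rec, "eeg_recording"))
  obj <- list(format = SESSION_FORMAT, version = SESSION_VERSION,
              rec = rec, labels = labels, result = result, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable or truncated session file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (!identical(obj$format, SESSION_FORMAT))
    stop("not a ", SESSION_FORMAT, " container: ", path)
  if (!identical(obj$version, SESSION_VERSION))
    stop("session container version ", obj$version,
         " not supported (expected ", SESSION_VERSION, ")")
  obj[c("rec", "labels", "result", "meta")]
}
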