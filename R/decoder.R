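LOG_POWER_FLOOR <- 1e-10  # microvolt^2 floor before the log

# features (length bands*2k) from per-band window covariance matrices
features_from_covs <- function(win_covs, csp) {
  unlist(lapply(seq_along(win_covs), function(bi) {
    Wsel <- csp_selected_filters(csp, bi)
    v <- diag(t(Wsel) %*% win_covs[[bi]] %*% Wsel)
    log(pmax(v, LOG_POWER_FLOOR))
  }), use.names = FALSE)
}

#' Extract the log band-power feature vector
#'
#' For each filterbank band, the trial is filtered causally, projected onto
#' the band's selected CSP filters, and the variance of each projection over
#' the 1-s window \code{[at_time_s - 1, at_time_s)} is floored and
#' log-transformed. Features are concatenated band-major: with the default
#' 15 bands and 6 projections per band this yields 90 features.
#'
#' @param trial a \code{\link{bci_trial}} or channels x samples matrix (from
#'   trial start).
#' @param csp a \code{\link{fit_csp_bank}} model.
#' @param fb the \code{\link{build_filterbank}} used for fitting.
#' @param at_time_s right edge of the 1-s feature window, seconds from trial
#'   start.
#' @param fs sampling rate (from the trial if it carries one).
#' @param band_signals optional precomputed \code{\link{apply_filterbank}}
#'   output for this trial (avoids re-filtering).
#' @return named numeric feature vector.
#' @export
extract_features <- function(trial, csp, fb, at_time_s, fs = NULL,
                             band_signals = NULL) {
  if (inherits(trial, "bci_trial")) { fs <- trial$fs; X <- trial$data }
  else { X <- as.matrix(trial); if (is.null(fs)) fs <- fb$fs }
  i1 <- round(at_time_s * fs)
  i0 <- round((at_time_s - 1) * fs)
  if (i0 < 0 || i1 > ncol(X))
    stop(sprintf("feature window [%g, %g) s underruns the available data",
                 at_time_s - 1, at_time_s))
  if (is.null(band_signals)) band_signals <- apply_filterbank(fb, X, fs = fs)
  win <- (i0 + 1L):i1
  feats <- unlist(lapply(seq_along(band_signals), function(bi) {
    Wsel <- csp_selected_filters(csp, bi)
    P <- t(Wsel) %*% band_signals[[bi]][, win, drop = FALSE]
    v <- apply(P, 1, stats::var)
    log(pmax(v, LOG_POWER_FLOOR))
  }))
  names(feats) <- as.vector(outer(seq_len(length(csp$bands[[1]]$selected)),
                                  names(band_signals),
                                  function(p, b) paste0(b, ".p", p)))
  feats
}

#' Bundle the three decoding stages into one versioned model
#'
#' @param fb filterbank, \code{\link{build_filterbank}}.
#' @param csp CSP bank, \code{\link{fit_csp_bank}}.
#' @param slda classifier, \code{\link{fit_slda}}.
#' @param provenance named list (retrain index, trials used, label source).
#' @return An object of class \code{decoder_model}.
#' @export
decoder_model <- function(fb, csp, slda, provenance = list()) {
  structure(list(fb = fb, csp = csp, slda = slda, provenance = provenance),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<decoder_model> %d bands x %d projections -> %d features; gamma = %.3f\n",
              length(x$csp$bands), length(x$csp$bands[[1]]$selected),
              length(x$slda$w), x$slda$gamma))
  if (length(p)) cat(" provenance:", paste(names(p), unlist(p), sep = "=",
                                           collapse = ", "), "\n")
  invisible(x)
}

# sliding variance of each row of P over trailing windows of win_n samples,
# evaluated at sample ends `ends` (1-based). Matches stats::var (n-1).
sliding_var <- function(P, win_n, ends) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  s1 <- cbind(0, t(apply(P, 1, cumsum)))
  s2 <- cbind(0, t(apply(P^2, 1, cumsum)))
  sum1 <- s1[, ends + 1, drop = FALSE] - s1[, ends - win_n + 1, drop = FALSE]
  sum2 <- s2[, ends + 1, drop = FALSE] - s2[, ends - win_n + 1, drop = FALSE]
  (sum2 - sum1^2 / win_n) / (win_n - 1)
}

#' Stream-classify a trial at the feedback output rate
#'
#' Emits one linear score every \code{fs / rate_hz} samples, starting as
#' soon as a full 1-s window of data is available (first output at 1.0 s).
#' Filtering is causal; no future samples are used. Predictions map
#' positive scores to class 2 ("feet"), non-positive to class 1.
#'
#' @param trial a \code{\link{bci_trial}} or channels x samples matrix.
#' @param model a \code{\link{decoder_model}}.
#' @param rate_hz output rate; must divide \code{fs}.
#' @param fs sampling rate (from the trial if it carries one).
#' @param band_signals optional precomputed filterbank output.
#' @return data.frame of class \code{score_series} with columns \code{time}
#'   (s, window right edge), \code{score}, \code{pred}.
#' @export
classify_stream <- function(trial, model, rate_hz = 16, fs = NULL,
                            band_signals = NULL) {
  stopifnot(inherits(model, "decoder_model"))
  if (inherits(trial, "bci_trial")) { fs <- trial$fs; X <- trial$data }
  else { X <- as.matrix(trial); if (is.null(fs)) fs <- model$fb$fs }
  if (fs %% rate_hz != 0)
    stop("rate_hz (", rate_hz, ") must divide the sampling rate (", fs, ")")
  step <- fs %/% rate_hz
  win_n <- fs
  ends <- seq.int(win_n, ncol(X), by = step)
  if (!length(ends)) stop("trial shorter than one analysis window")
  if (is.null(band_signals)) band_signals <- apply_filterbank(model$fb, X, fs = fs)
  feats <- do.call(rbind, lapply(seq_along(band_signals), function(bi) {
    Wsel <- csp_selected_filters(model$csp, bi)
    P <- Wsel_project(Wsel, band_signals[[bi]])
    v <- sliding_var(P, win_n, ends)
    log(pmax(v, LOG_POWER_FLOOR))
  }))
  scores <- drop(crossprod(feats, model$slda$w)) + model$slda$b
  cls <- model$slda$classes
  out <- data.frame(time = ends / fs, score = scores,
                    pred = ifelse(scores > 0, cls[2], cls[1]))
  class(out) <- c("score_series", class(out))
  out
}

Wsel_project <- function(Wsel, Xband) t(Wsel) %*% Xband
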