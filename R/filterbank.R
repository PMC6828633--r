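#' Default filterbank bands
#'
#' The 15 overlapping bandpass bands (Hz) covering the mu and beta range:
#' seven 2-Hz-wide mu bands (6-8 through 12-14 Hz) and eight 5-Hz-wide beta
#' bands (14-19 through 35-40 Hz).
#' @return 15 x 2 numeric matrix with columns \code{low}, \code{high}.
#' @export
default_bands <- function() {
  mu <- cbind(6:12, 8:14)
  beta_lo <- seq(14, 35, by = 3)
  beta <- cbind(beta_lo, beta_lo + 5)
  out <- rbind(mu, beta)
  dimnames(out) <- list(NULL, c("low", "high"))
  out
}

#' Build the IIR bandpass filterbank
#'
#' Designs one Butterworth bandpass filter per band. \code{order} is the
#' overall order of each bandpass filter (8 poles for the default), i.e. the
#' lowpass prototype has order \code{order/2}. Butterworth is used for its
#' flat passband, which avoids band-power bias; the family is encapsulated
#' here and can be swapped by replacing this constructor.
#'
#' @param bands numeric matrix (n x 2) of band edges in Hz; default the 15
#'   mu/beta bands of \code{\link{default_bands}}.
#' @param order overall bandpass filter order (even).
#' @param fs sampling rate the filters are designed for, Hz.
#' @return An object of class \code{filter_bank}.
#' @export
build_filterbank <- function(bands = default_bands(), order = 8, fs = 256) {
  bands <- as.matrix(bands)
  if (ncol(bands) != 2) stop("bands must be an n x 2 matrix")
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even integer")
  if (any(bands[, 1] <= 0) || any(bands[, 1] >= bands[, 2]))
    stop("each band must satisfy 0 < low < high")
  if (any(bands[, 2] >= fs / 2))
    stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  filters <- lapply(seq_len(nrow(bands)), function(i) {
    fl <- signal::butter(order / 2, bands[i, ] / (fs / 2), type = "pass")
    poles <- polyroot(rev(fl$a))
    if (any(Mod(poles) >= 1))
      stop(sprintf("unstable filter for band %g-%g Hz", bands[i, 1], bands[i, 2]))
    list(b = fl$b, a = fl$a)
  })
  structure(list(bands = bands, order = order, fs = fs, filters = filters,
                 band_names = sprintf("%g-%gHz", bands[, 1], bands[, 2])),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d Butterworth bandpass filters (order %d) @ %g Hz\n",
              nrow(x$bands), x$order, x$fs))
  cat(" bands:", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}

# Causal IIR filtering of a channels x samples matrix with zero initial
# conditions. Uses stats::filter (C code) column-wise on the transposed
# signal; numerically identical to signal::filter on each channel.
iir_apply <- function(b, a, X) {
  one_chan <- is.null(dim(X))
  Xt <- if (one_chan) matrix(X, ncol = 1) else t(X)
  nb <- length(b)
  pad <- matrix(0, nb - 1L, ncol(Xt))
  conv <- stats::filter(rbind(pad, Xt), b, method = "convolution", sides = 1)
  conv <- conv[nb:nrow(conv), , drop = FALSE]
  out <- stats::filter(conv, -a[-1], method = "recursive")
  out <- matrix(as.numeric(out), nrow = nrow(Xt))
  if (one_chan) drop(out) else t(out)
}

# single-band causal bandpass of a channels x samples matrix
bandpass_causal <- function(X, band, fs, order = 8) {
  fl <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  iir_apply(fl$b, fl$a, X)
}

#' Apply the filterbank
#'
#' Causally filters a signal with every band of the filterbank (single
#' forward pass, zero initial state: no future samples are used, matching
#' online operation).
#'
#' @param fb a \code{\link{build_filterbank}} object.
#' @param x an \code{\link{eeg_recording}}, a \code{\link{bci_trial}}, or a
#'   channels x samples matrix.
#' @param fs sampling rate of \code{x} when it is a bare matrix.
#' @return named list with one channels x samples matrix per band.
#' @export
apply_filterbank <- function(fb, x, fs = NULL) {
  stopifnot(inherits(fb, "filter_bank"))
  if (inherits(x, "eeg_recording")) { fs <- x$fs; x <- x$signal }
  else if (inherits(x, "bci_trial")) { fs <- x$fs; x <- x$data }
  else if (is.null(fs)) fs <- fb$fs
  if (fs != fb$fs)
    stop("sampling rate of input (", fs, " Hz) does not match filterbank design (",
         fb$fs, " Hz)")
  out <- lapply(fb$filters, function(fl) iir_apply(fl$b, fl$a, x))
  names(out) <- fb$band_names
  out
}
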