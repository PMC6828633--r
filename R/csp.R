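# Ledoit-Wolf-style analytic shrinkage intensity for a class covariance
# estimated as the mean of per-trial covariance matrices: dispersion of the
# per-trial covariances around their mean versus distance of the mean from
# the scaled-identity target.
shrinkage_from_trial_covs <- function(covs) {
  n <- length(covs)
  d <- nrow(covs[[1]])
  cbar <- Reduce(`+`, covs) / n
  target <- diag(mean(diag(cbar)), d)
  denom <- sum((cbar - target)^2)
  if (denom <= 0 || n < 2) return(0)
  num <- sum(vapply(covs, function(C) sum((C - cbar)^2), numeric(1))) / (n * (n - 1))
  min(1, max(0, num / denom))
}

shrink_toward_identity <- function(C, lambda) {
  d <- nrow(C)
  (1 - lambda) * C + lambda * diag(mean(diag(C)), d)
}

# Joint diagonalization of two SPD matrices via whitening of their sum.
# Returns filters W (columns), eigenvalues of class 1 in whitened space
# (descending), and patterns A = inverse of t(W).
csp_decompose <- function(C1, C2) {
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- max(ec$values) * nrow(Cc) * .Machine$double.eps
  if (min(ec$values) < tol)
    stop("composite covariance is rank deficient; use nonzero CSP shrinkage")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)    # whitener: P Cc P' = I
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  es <- eigen(S1, symmetric = TRUE)                   # values descending
  W <- t(P) %*% es$vectors
  list(W = W, eigenvalues = es$values)
}

# per-trial covariance of the CSP training epoch of a band-filtered trial
epoch_cov <- function(Xband, timing, fs) {
  idx <- time_window_idx(timing$csp_epoch[1], timing$csp_epoch[2], fs)
  stats::cov(t(Xband[, idx, drop = FALSE]))
}

# core fit from per-band lists of per-trial covariances
fit_csp_bank_from_covs <- function(cov_by_band, labels, band_names,
                                   shrinkage = NULL, n_select = 3) {
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("CSP needs exactly 2 classes; got ", length(classes))
  if (any(table(labels) < 2)) stop("CSP needs >= 2 trials per class")
  bands <- lapply(seq_along(cov_by_band), function(bi) {
    covs <- cov_by_band[[bi]]
    c1 <- covs[labels == classes[1]]
    c2 <- covs[labels == classes[2]]
    lam <- if (is.null(shrinkage))
      c(shrinkage_from_trial_covs(c1), shrinkage_from_trial_covs(c2))
    else rep(shrinkage, length.out = 2)
    C1 <- shrink_toward_identity(Reduce(`+`, c1) / length(c1), lam[1])
    C2 <- shrink_toward_identity(Reduce(`+`, c2) / length(c2), lam[2])
    dec <- csp_decompose(C1, C2)
    d <- ncol(dec$W)
    k <- min(n_select, floor(d / 2))
    sel <- c(seq_len(k), seq.int(d - k + 1L, d))
    list(W = dec$W, eigenvalues = dec$eigenvalues, selected = sel,
         shrinkage = lam)
  })
  names(bands) <- band_names
  structure(list(bands = bands, classes = classes, n_select = n_select),
            class = "csp_bank")
}

#' Fit a per-band shrinkage-regularized CSP filter bank
#'
#' For every filterbank band, class covariance matrices are averaged over
#' the per-trial covariances of the 4.75-7.75 s training epoch, shrunk
#' toward a scaled identity (analytic Ledoit-Wolf-style intensity unless
#' \code{shrinkage} fixes it), and jointly diagonalized. Filters (columns of
#' W) are ordered by descending eigenvalue of the class-1 ("hand")
#' covariance in the whitened space; the first three and last three are
#' selected, giving the projections with the most extreme between-class
#' variance ratios.
#'
#' @param trials list of \code{\link{bci_trial}} or channels x samples
#'   matrices (full trials from trial start).
#' @param labels integer class labels (2 classes).
#' @param fb a \code{\link{build_filterbank}} object.
#' @param timing a \code{\link{trial_timing}} (supplies the CSP epoch).
#' @param fs sampling rate (from trials if they carry one).
#' @param shrinkage fixed shrinkage intensity in [0,1], or \code{NULL} for
#'   the analytic estimate (per class).
#' @param n_select projections kept from each end of the eigenvalue
#'   spectrum (default 3, i.e. 6 per band).
#' @return An object of class \code{csp_bank}.
#' @export
fit_csp_bank <- function(trials, labels, fb, timing = trial_timing(),
                         fs = NULL, shrinkage = NULL, n_select = 3) {
  mats <- lapply(trials, function(tr) if (inherits(tr, "bci_trial")) tr$data else as.matrix(tr))
  if (is.null(fs))
    fs <- if (inherits(trials[[1]], "bci_trial")) trials[[1]]$fs else fb$fs
  cov_by_band <- lapply(seq_along(fb$filters), function(bi) {
    fl <- fb$filters[[bi]]
    lapply(mats, function(X) epoch_cov(iir_apply(fl$b, fl$a, X), timing, fs))
  })
  fit_csp_bank_from_covs(cov_by_band, labels, fb$band_names,
                         shrinkage = shrinkage, n_select = n_select)
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf("<csp_bank> %d bands, %d selected projections per band\n",
              length(x$bands), length(x$bands[[1]]$selected)))
  invisible(x)
}

# selected spatial filter matrix (channels x 2k) for band bi
csp_selected_filters <- function(csp, bi) {
  b <- csp$bands[[bi]]
  b$W[, b$selected, drop = FALSE]
}
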