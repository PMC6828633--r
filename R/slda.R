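# Ledoit-Wolf analytic shrinkage intensity toward nu*I from (class-)centered
# samples Z (n x d): gamma = min(b2, d2) / d2 with d2 the dispersion of S
# around the target and b2 the estimation variance of S.
ledoit_wolf_gamma <- function(Z) {
  n <- nrow(Z); d <- ncol(Z)
  if (n < 2) return(1)
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / d
  d2 <- sum((S - diag(nu, d))^2) / d
  if (d2 <= 0) return(0)
  x2 <- rowSums(Z^2)
  quad <- rowSums((Z %*% S) * Z)
  b2 <- sum(x2^2 - 2 * quad + sum(S^2)) / (n^2 * d)
  min(1, max(0, min(b2, d2) / d2))
}

#' Fit a shrinkage-regularized LDA classifier
#'
#' Binary linear discriminant with the pooled within-class covariance
#' shrunk toward a scaled identity: \code{Sigma = (1-gamma) S +
#' gamma (tr(S)/d) I}, with \code{gamma} chosen by the analytic
#' Ledoit-Wolf estimator unless fixed. The weight vector is
#' \code{w = Sigma^-1 (mu2 - mu1)} and the bias places the decision
#' boundary midway between the projected class means. The linear score is
#' \code{s(x) = w.x + b}; positive scores vote for class 2 ("feet"),
#' scores of exactly 0 are broken deterministically to class 1. Shrinkage
#' keeps the weights finite even when features far outnumber trials.
#'
#' @param x numeric matrix, samples x features.
#' @param y integer class labels (2 classes, >= 2 samples each).
#' @param gamma fixed shrinkage intensity in [0,1], or \code{NULL} for the
#'   analytic estimate.
#' @return An object of class \code{slda_model} with elements \code{w},
#'   \code{b}, \code{gamma}, \code{means}, \code{sigma}, \code{classes}.
#' @export
fit_slda <- function(x, y, gamma = NULL) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("sLDA needs exactly 2 classes")
  if (any(table(y) < 2)) stop("sLDA needs >= 2 samples per class")
  mu1 <- colMeans(x[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(x[y == classes[2], , drop = FALSE])
  Z <- x
  Z[y == classes[1], ] <- sweep(x[y == classes[1], , drop = FALSE], 2, mu1)
  Z[y == classes[2], ] <- sweep(x[y == classes[2], , drop = FALSE], 2, mu2)
  if (is.null(gamma)) gamma <- ledoit_wolf_gamma(Z)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  d <- ncol(x)
  S <- crossprod(Z) / nrow(Z)
  sigma <- (1 - gamma) * S + gamma * diag(sum(diag(S)) / d, d)
  w <- drop(solve(sigma, mu2 - mu1))
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, b = b, gamma = gamma,
                 means = rbind(mu1, mu2), sigma = sigma, classes = classes),
            class = "slda_model")
}

#' Linear scores and predictions of an sLDA model
#'
#' @param object an \code{\link{fit_slda}} model.
#' @param newdata samples x features matrix or single feature vector.
#' @param ... unused.
#' @return data.frame with columns \code{score} and \code{pred}.
#' @export
predict.slda_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  s <- drop(newdata %*% object$w) + object$b
  data.frame(score = s,
             pred = ifelse(s > 0, object$classes[2], object$classes[1]))
}
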