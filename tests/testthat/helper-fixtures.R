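# Small in-code fixtures shared across test files.

# quick small session: few trials per class, short policy numbers
small_session <- function(seed = 1, n_tpc = 8, erd_depth = 0.5, ...) {
  generate_session(synth_config(seed = seed, n_tpc = n_tpc,
                                erd_depth = erd_depth, ...))
}

small_policy <- function(mode = "supervised", first = 3, inc = 2, calib = 5) {
  retrain_policy(mode, first_training_tpc = first, increment_tpc = inc,
                 supervised_calibration_tpc = calib)
}

# trials of pure gaussian noise, channels x samples
noise_trials <- function(n, n_ch = 4, n_samp = 512, sd = 10, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(n_ch * n_samp, sd = sd), n_ch))
}

# random SPD matrix
rand_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}

# brute-force generalized eigenproblem oracle: C1 v = lambda (C1 + C2) v
# via the (non-symmetric) matrix solve(C1 + C2) %*% C1
geigen_oracle <- function(C1, C2) {
  M <- solve(C1 + C2) %*% C1
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}
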