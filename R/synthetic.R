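#' Synthetic session configuration
#'
#' Parameters of the two-class ERD EEG generator. The generator emulates
#' right-hand vs. both-feet motor imagery: band-limited mu (8-12 Hz) and
#' beta (16-24 Hz) oscillatory sources ride on 1/f background noise; during
#' the imagery period of a trial the source matching that trial's class is
#' attenuated (event-related desynchronization). The hand-imagery source is
#' centred on contralateral C3, the feet source centrally on Cz, each spread
#' to its four orthogonal neighbours by a fixed mixing gain so that the
#' classes differ in spatial covariance (what CSP exploits) and not merely
#' in single-channel power.
#'
#' @param seed RNG seed; identical configs with identical seeds produce
#'   bit-identical sessions.
#' @param n_tpc trials per class.
#' @param fs sampling rate, Hz.
#' @param timing a \code{\link{trial_timing}}.
#' @param spec a \code{\link{session_spec}}; its \code{n_tpc} is overridden
#'   by \code{n_tpc}.
#' @param noise_exponent slope of the 1/f background (PSD proportional to
#'   f^-noise_exponent).
#' @param noise_scale RMS of the background noise per channel, microvolts.
#' @param mu_band,beta_band oscillatory source bands, Hz.
#' @param osc_amp_mu,osc_amp_beta RMS amplitude of the mu and beta sources
#'   at their central channel, microvolts.
#' @param erd_depth fractional amplitude attenuation in [0,1] of the
#'   class-matching sources during imagery. Scalar, or a 2 x 2 matrix with
#'   rows (hand, feet) and columns (mu, beta).
#' @param mixing gain with which each source leaks into the four orthogonal
#'   neighbours of its central channel.
#' @param erd_ramp_s duration of the raised-cosine ERD onset/offset ramp.
#' @param artifact_rate probability that a trial receives a high-amplitude
#'   transient.
#' @param artifact_amp peak amplitude of injected transients, microvolts
#'   (choose > 125 to trip the amplitude rejection rule).
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1, n_tpc = 190, fs = 256,
                         timing = trial_timing(),
                         spec = session_spec(n_tpc = n_tpc,
                           break_positions = c(40, 90, 140)[c(40, 90, 140) < n_tpc]),
                         noise_exponent = 1, noise_scale = 6,
                         mu_band = c(8, 12), beta_band = c(16, 24),
                         osc_amp_mu = 5, osc_amp_beta = 3,
                         erd_depth = 0.2, mixing = 0.35,
                         erd_ramp_s = 0.5,
                         artifact_rate = 0, artifact_amp = 0) {
  if (is.matrix(erd_depth)) {
    if (!all(dim(erd_depth) == c(2, 2))) stop("matrix erd_depth must be 2 x 2")
  } else {
    erd_depth <- matrix(erd_depth, 2, 2)
  }
  dimnames(erd_depth) <- list(c("hand", "feet"), c("mu", "beta"))
  if (any(erd_depth < 0) || any(erd_depth > 1))
    stop("erd_depth must lie in [0, 1]")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  structure(list(seed = seed, n_tpc = n_tpc, fs = fs, timing = timing,
                 spec = spec, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, mu_band = mu_band,
                 beta_band = beta_band, osc_amp_mu = osc_amp_mu,
                 osc_amp_beta = osc_amp_beta, erd_depth = erd_depth,
                 mixing = mixing, erd_ramp_s = erd_ramp_s,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp),
            class = "synth_config")
}

# 1/f^alpha gaussian noise, length n, unit RMS (alpha = 0 -> white)
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w / stats::sd(w))
  W <- stats::fft(w)
  f <- c(1e-6, seq_len(n - 1))            # cycles per record; suppress DC
  f <- pmin(f, n - f)                     # two-sided frequency magnitude
  shape <- f^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# orthogonal-neighbour map of the default montage
laplacian_neighbours <- function() {
  list(C3 = c("C1", "C5", "FC3", "CP3"),
       Cz = c("C1", "C2", "FCz", "CPz"),
       C4 = c("C2", "C6", "FC4", "CP4"))
}

# per-class balanced trial order, run by run
synth_label_order <- function(n_tpc, run_tpc) {
  n_runs <- ceiling(n_tpc / run_tpc)
  unlist(lapply(seq_len(n_runs), function(r) {
    k <- min(run_tpc, n_tpc - (r - 1) * run_tpc)
    sample(rep(c(1L, 2L), each = k))
  }))
}

#' Generate a synthetic two-class motor-imagery session
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list with elements \code{rec} (an \code{\link{eeg_recording}}
#'   whose event codes are the true labels), \code{labels} (integer vector,
#'   one per trial), and \code{artifact_trials} (indices of trials that
#'   received an injected transient).
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  chans <- default_channels()
  n_ch <- length(chans)
  trial_len <- round(cfg$timing$trial_len_s * fs)
  block <- trial_len + round(cfg$spec$inter_trial_interval_s * fs)
  labels <- synth_label_order(cfg$n_tpc, cfg$spec$run_tpc)
  n_trials <- length(labels)
  n_samp <- n_trials * block

  # background 1/f noise, independent per channel
  sig <- matrix(0, n_ch, n_samp)
  for (c in seq_len(n_ch))
    sig[c, ] <- cfg$noise_scale * pink_noise(n_samp, cfg$noise_exponent)

  # ERD envelope per class: 1 - depth * g(t), g ramping over erd_ramp_s
  ramp_n <- round(cfg$erd_ramp_s * fs)
  gate_one <- function() {
    g <- numeric(block)
    i0 <- round(cfg$timing$imagery_start_s * fs)
    i1 <- trial_len
    g[(i0 + 1):i1] <- 1
    if (ramp_n > 1) {
      up <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
      g[(i0 + 1):(i0 + ramp_n)] <- up
      end <- min(i1 + ramp_n, block)
      if (end > i1) g[(i1 + 1):end] <- rev(up)[seq_len(end - i1)]
    }
    g
  }
  g_trial <- gate_one()
  gate <- function(class_id) {       # full-session 0/1 ERD gate for a class
    out <- numeric(n_samp)
    idx <- which(labels == class_id)
    for (i in idx) out[((i - 1) * block + 1):(i * block)] <- g_trial
    out
  }
  gates <- list(hand = gate(1L), feet = gate(2L))

  nb <- laplacian_neighbours()
  sources <- list(
    list(class = "hand", centre = "C3", band = cfg$mu_band,
         amp = cfg$osc_amp_mu,   depth = cfg$erd_depth["hand", "mu"]),
    list(class = "hand", centre = "C3", band = cfg$beta_band,
         amp = cfg$osc_amp_beta, depth = cfg$erd_depth["hand", "beta"]),
    list(class = "feet", centre = "Cz", band = cfg$mu_band,
         amp = cfg$osc_amp_mu,   depth = cfg$erd_depth["feet", "mu"]),
    list(class = "feet", centre = "Cz", band = cfg$beta_band,
         amp = cfg$osc_amp_beta, depth = cfg$erd_depth["feet", "beta"]))
  for (src in sources) {
    osc <- bandpass_causal(stats::rnorm(n_samp), src$band, fs, order = 4)
    osc <- osc / sqrt(mean(osc^2)) * src$amp
    env <- 1 - src$depth * gates[[src$class]]
    osc <- osc * env
    gains <- numeric(n_ch)
    gains[match(src$centre, chans)] <- 1
    gains[match(nb[[src$centre]], chans)] <- cfg$mixing
    sig <- sig + outer(gains, osc)
  }

  events <- data.frame(sample = (seq_len(n_trials) - 1L) * block,
                       code = labels)
  rec <- eeg_recording(sig, fs = fs, channel_labels = chans, events = events)

  artifact_trials <- integer(0)
  if (cfg$artifact_rate > 0 && cfg$artifact_amp > 0) {
    inj <- inject_artifacts(rec, cfg$artifact_rate, cfg$artifact_amp,
                            timing = cfg$timing)
    rec <- inj$rec
    artifact_trials <- inj$affected
  }
  list(rec = rec, labels = labels, artifact_trials = artifact_trials)
}

#' Inject high-amplitude transients into trials
#'
#' Adds, with probability \code{rate} per trial, a Hann-windowed 8-Hz burst
#' (250 ms) of peak amplitude \code{amp} microvolts on one to three random
#' channels. The burst lies inside the 3-35 Hz rejection passband, so with
#' \code{amp} well above 125 microvolts it reliably trips the amplitude
#' rejection rule.
#'
#' @param rec an \code{\link{eeg_recording}} with trial-start events.
#' @param rate probability per trial of receiving a transient.
#' @param amp peak amplitude, microvolts.
#' @param seed optional seed; if \code{NULL}, the current RNG stream is
#'   used.
#' @param timing a \code{\link{trial_timing}}.
#' @return list with \code{rec} (modified recording) and \code{affected}
#'   (indices of modified trials).
#' @export
inject_artifacts <- function(rec, rate, amp, seed = NULL,
                             timing = trial_timing()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || amp == 0)
    return(list(rec = rec, affected = integer(0)))
  fs <- rec$fs
  trial_len <- round(timing$trial_len_s * fs)
  burst_n <- round(0.25 * fs)
  tt <- seq_len(burst_n) / fs
  burst <- sin(2 * pi * 8 * tt) * (1 - cos(2 * pi * seq_len(burst_n) / burst_n)) / 2
  burst <- burst / max(abs(burst))
  sig <- rec$signal
  n_trials <- nrow(rec$events)
  hit <- stats::runif(n_trials) < rate
  for (i in which(hit)) {
    s0 <- rec$events$sample[i]
    at <- s0 + sample.int(trial_len - burst_n, 1)
    ch <- sample.int(nrow(sig), sample(1:3, 1))
    sgn <- sample(c(-1, 1), 1)
    sig[ch, (at + 1):(at + burst_n)] <-
      sig[ch, (at + 1):(at + burst_n), drop = FALSE] +
      rep(sgn * amp * burst, each = length(ch))
  }
  list(rec = eeg_recording(sig, rec$fs, rec$channel_labels, rec$events),
       affected = which(hit))
}
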