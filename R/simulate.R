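# Forward-model simulator of three-class motor-imagery EEG.
#
# Sensors = A_true %*% sources + white sensor noise. Three of the sources
# are motor-related components (MRICs) with Gaussian spatial profiles
# centered on C3, Cz and C4; per trial, contralateral event-related
# desynchronization (ERD) attenuates exactly one MRIC's mu power during the
# imagery window: class 1 (left hand) -> C4 source, class 2 (right hand) ->
# C3 source, class 3 (foot) -> Cz source. Remaining sources are pink-noise
# background with random smooth topographies. Physiological artifacts
# (blinks, occipital alpha) and broadband burst interferences can be added.

#' Simulation configuration
#'
#' @param n_channels 8 or 9 (the two reduced montages; see
#'   [channel_scheme]).
#' @param fs Sampling rate in Hz.
#' @param trial_s Trial length in seconds.
#' @param n_trials_per_class Trials per class (3 classes).
#' @param subject_band Length-2 Hz band carrying the mu-rhythm sources
#'   (e.g. `c(10, 14)`).
#' @param erd_depth Fractional mu-power retained during imagery by the
#'   attenuated source, in `(0, 1]`: 1 means no ERD (classes are
#'   indistinguishable), 0.5 halves the power.
#' @param snr_db Sensor-noise level: ratio of mean signal power to white
#'   sensor-noise power, in dB.
#' @param erd_window Length-2 seconds relative to trial onset during which
#'   ERD applies.
#' @param mod_depth Depth of the slow amplitude modulation of the mu
#'   carriers (makes them super-Gaussian, as real mu bursts are).
#' @param source_scale Scalp amplitude scale in microvolts: std of each
#'   source's contribution at its peak electrode.
#' @param artifacts List of artifact descriptors, each a list with `type`
#'   (`"blink"`, `"alpha"` or `"burst"`), `amplitude` (microvolts for
#'   blink/alpha; multiple of channel std for burst), `rate` (events/s,
#'   blink only), and `trials` (trial indices; `NULL` = whole recording for
#'   blink/alpha, required for burst).
#' @param seed Integer seed; the simulation is a deterministic function of
#'   the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 9, fs = 250, trial_s = 10,
                       n_trials_per_class = 25, subject_band = c(10, 14),
                       erd_depth = 0.5, snr_db = 10,
                       erd_window = c(0.5, 5), mod_depth = 0.3,
                       source_scale = 10, artifacts = list(), seed = 1) {
  if (!n_channels %in% c(8, 9)) stop("n_channels must be 8 or 9")
  if (!(erd_depth > 0 && erd_depth <= 1)) stop("erd_depth must be in (0, 1]")
  if (n_trials_per_class < 1) stop("need at least one trial per class")
  if (!(erd_window[1] >= 0 && erd_window[1] < erd_window[2] &&
        erd_window[2] <= trial_s))
    stop("erd_window must lie inside the trial")
  structure(list(n_channels = n_channels, fs = fs, trial_s = trial_s,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 subject_band = subject_band, erd_depth = erd_depth,
                 snr_db = snr_db, erd_window = erd_window,
                 mod_depth = mod_depth, source_scale = source_scale,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "sim_config")
}

# 1/f ("pink") noise via FFT spectral shaping, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  X <- X / sqrt(pmax(f, 1))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited Gaussian noise (FFT brick-wall + taper), unit variance.
band_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  keep <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(X * keep, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slow (< cutoff Hz) modulation noise, unit variance.
slow_noise <- function(n, fs, cutoff = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  keep <- as.numeric(f > 0 & f <= cutoff)
  x <- Re(stats::fft(X * keep, inverse = TRUE)) / n
  x / stats::sd(x)
}

gaussian_topo <- function(coords, center, sigma = 0.4) {
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2
  exp(-d2 / (2 * sigma^2))
}

#' Generate a synthetic three-class motor-imagery run
#'
#' Builds a continuous labeled recording from the forward model described
#' in [sim_config], together with its ground truth (true mixing matrix,
#' source roles, trial labels, artifact bookkeeping).
#'
#' @param cfg A [sim_config].
#' @param A_true Optional mixing matrix from a previous simulation of the
#'   same montage: reusing it emulates a second run / session from the
#'   same subject (same head geometry, fresh sources, noise and labels),
#'   the setting for run-to-run or session-to-session transfer.
#' @return An object of class `mi_simulation`: a list with `recording`
#'   (an [eeg_recording]) and `truth` (list with `A_true`, `source_roles`
#'   — indices of the C3/Cz/C4 sources —, `labels`, `artifact_trials`,
#'   `erd_window`, and the true MRIC source time courses `sources_mric`).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_trials_per_class = 2, seed = 42))
#' sim$recording
generate_dataset <- function(cfg, A_true = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  scheme <- channel_scheme(if (cfg$n_channels == 9) "nine" else "eight")
  labels <- scheme$labels
  N <- length(labels)
  coords <- montage_coords(labels)
  fs <- cfg$fs
  L <- round(cfg$trial_s * fs)
  n_trials <- 3L * cfg$n_trials_per_class
  T_total <- n_trials * L

  # trial labels: 25 per class in randomized order
  trial_labels <- sample(rep(1:3, cfg$n_trials_per_class))

  # mixing matrix: sources 1..3 are the C3/Cz/C4 MRICs, with compact
  # Gaussian profiles (width ~ one inter-electrode spacing); background
  # sources get random smooth topographies, redrawn if the mixing matrix
  # comes out badly conditioned (a badly conditioned forward model is not
  # a physiologically interesting failure mode).
  if (is.null(A_true)) {
    mric_ch <- c("C3", "Cz", "C4")
    A <- matrix(0, N, N)
    for (j in 1:3) A[, j] <- gaussian_topo(coords, coords[mric_ch[j], ],
                                           sigma = 0.3)
    bg_sites <- matrix(c(-0.35, 0.95,   0.35, 0.95,  -0.90, 0.30,
                          0.90, 0.30,  -0.60, -0.70,  0.60, -0.70,
                          0.00, -1.00,  0.00, 0.72,  -0.90, -0.30,
                          0.90, -0.30), ncol = 2, byrow = TRUE)
    for (attempt in 1:50) {
      ctrs <- bg_sites[sample(nrow(bg_sites), N - 3L), , drop = FALSE] +
        matrix(stats::runif(2L * (N - 3L), -0.1, 0.1), ncol = 2)
      for (j in 4:N)
        A[, j] <- gaussian_topo(coords, ctrs[j - 3L, ],
                                sigma = stats::runif(1, 0.3, 0.45))
      if (kappa(A, exact = TRUE) < 25) break
    }
    # peak-normalize columns; amplitude lives in the sources
    A <- sweep(A, 2, apply(abs(A), 2, max), "/")
  } else {
    A <- as.matrix(A_true)
    if (!all(dim(A) == N))
      stop("A_true must be ", N, " x ", N, " for this montage")
  }

  # sources: mu-band carriers with slow amplitude modulation, power
  # calibrated per trial (unit variance inside and outside the imagery
  # window) so that erd_depth is the realized mu-power attenuation, not
  # merely its expectation — a 4 Hz-wide Gaussian carrier's intrinsic
  # power fluctuation over a few seconds would otherwise drown a 3 dB ERD.
  w0 <- round(cfg$erd_window[1] * fs)
  w1 <- round(cfg$erd_window[2] * fs)
  S <- matrix(0, N, T_total)
  for (j in 1:3) {
    carrier <- band_noise(T_total, fs, cfg$subject_band)
    env <- 1 + cfg$mod_depth * slow_noise(T_total, fs, cutoff = 1)
    s <- carrier * pmax(env, 0.2)
    for (i in seq_len(n_trials)) {
      base <- (i - 1L) * L
      win <- (base + w0 + 1L):(base + w1)
      rest <- setdiff((base + 1L):(base + L), win)
      s[win] <- s[win] / stats::sd(s[win])
      s[rest] <- s[rest] / stats::sd(s[rest])
    }
    S[j, ] <- s
  }
  for (j in 4:N) S[j, ] <- pink_noise(T_total)

  # ERD: attenuate the class-specific contralateral source during imagery
  erd_target <- c(3L, 1L, 2L)  # class -> source row (C4, C3, Cz)
  amp_factor <- sqrt(cfg$erd_depth)
  for (i in seq_len(n_trials)) {
    tgt <- erd_target[trial_labels[i]]
    idx <- ((i - 1L) * L + w0 + 1L):((i - 1L) * L + w1)
    S[tgt, idx] <- S[tgt, idx] * amp_factor
  }

  X <- cfg$source_scale * (A %*% S)

  # physiological artifacts are extra sources layered on top
  artifact_trials <- integer(0)
  burst_specs <- list()
  for (a in cfg$artifacts) {
    type <- a$type %||% stop("artifact needs a type")
    if (type == "blink") {
      X <- X + blink_artifact(a, coords, n_trials, L, fs)
    } else if (type == "alpha") {
      X <- X + alpha_artifact(a, coords, n_trials, L, fs)
    } else if (type == "burst") {
      burst_specs <- c(burst_specs, list(a))
    } else stop("unknown artifact type: ", type)
  }

  # sensor noise at snr_db
  sig_pow <- mean(X^2)
  noise_sd <- sqrt(sig_pow / 10^(cfg$snr_db / 10))
  X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow = N)

  events <- data.frame(onset = (seq_len(n_trials) - 1L) * L + 1L,
                       label = trial_labels)
  rec <- eeg_recording(X, fs, labels, events)
  truth <- list(A_true = A, source_roles = c(C3 = 1L, Cz = 2L, C4 = 3L),
                labels = trial_labels, artifact_trials = artifact_trials,
                erd_window = cfg$erd_window, source_scale = cfg$source_scale,
                sources_mric = S[1:3, , drop = FALSE])
  sim <- structure(list(recording = rec, truth = truth, config = cfg),
                   class = "mi_simulation")

  # burst interferences injected post hoc so they ride on the mixed signal
  for (a in burst_specs) {
    if (is.null(a$trials)) stop("burst artifact needs target trials")
    for (tr in a$trials) {
      sim <- inject_burst(sim, tr,
                          t0 = a$t0 %||% stats::runif(1, 0.5, cfg$trial_s - 1.5),
                          dur = a$dur %||% stats::runif(1, 0.5, 1),
                          amp = a$amplitude %||% 10,
                          channels = a$channels)
    }
  }
  sim
}

#' @export
print.mi_simulation <- function(x, ...) {
  cat("<mi_simulation>\n  ")
  print(x$recording)
  cat(sprintf("  ERD depth %.2f in [%g, %g] s; artifact trials: %s\n",
              x$config$erd_depth, x$truth$erd_window[1], x$truth$erd_window[2],
              if (length(x$truth$artifact_trials))
                paste(sort(unique(x$truth$artifact_trials)), collapse = ", ")
              else "none"))
  invisible(x)
}

blink_artifact <- function(a, coords, n_trials, L, fs) {
  N <- nrow(coords)
  T_total <- n_trials * L
  out <- matrix(0, N, T_total)
  rate <- a$rate %||% 0.2
  amp <- a$amplitude %||% 80
  trials <- a$trials %||% seq_len(n_trials)
  topo <- gaussian_topo(coords, c(0, 1.1), sigma = 0.5)
  # biphasic pulse: derivative-of-Gaussian, ~0.4 s support
  tt <- seq(-0.2, 0.2, by = 1 / fs)
  pulse <- -tt * exp(-tt^2 / (2 * 0.06^2))
  pulse <- amp * pulse / max(abs(pulse))
  n_ev <- stats::rpois(1, rate * length(trials) * L / fs)
  if (n_ev > 0) {
    tr <- sample(trials, n_ev, replace = TRUE)
    within <- stats::runif(n_ev, 0.25, L / fs - 0.25)
    for (k in seq_len(n_ev)) {
      c0 <- (tr[k] - 1L) * L + round(within[k] * fs)
      idx <- c0 + seq_along(pulse) - (length(pulse) %/% 2L)
      ok <- idx >= 1 & idx <= T_total
      out[, idx[ok]] <- out[, idx[ok]] +
        outer(topo, pulse[ok])
    }
  }
  out
}

alpha_artifact <- function(a, coords, n_trials, L, fs) {
  N <- nrow(coords)
  T_total <- n_trials * L
  amp <- a$amplitude %||% 20
  trials <- a$trials %||% seq_len(n_trials)
  topo <- gaussian_topo(coords, c(0, -1.05), sigma = 0.5)
  t <- seq_len(T_total) / fs
  osc <- sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
  gate <- pmax(slow_noise(T_total, fs, cutoff = 0.3), 0)  # waxing/waning
  mask <- rep(0, T_total)
  for (tr in trials) mask[((tr - 1L) * L + 1L):(tr * L)] <- 1
  outer(topo, amp * osc * gate * mask)
}

#' Inject a broadband burst interference into one trial
#'
#' Adds a high-amplitude broadband transient (white noise shaped by a Tukey
#' taper) to the stated channels of one trial, emulating the
#' non-physiological interferences caused by body movement or electrode
#' loosening. The simulation's ground-truth `artifact_trials` set is
#' updated.
#'
#' @param sim An `mi_simulation` from [generate_dataset].
#' @param trial_idx 1-based trial to contaminate.
#' @param t0 Burst onset in seconds relative to the trial start.
#' @param dur Burst duration in seconds (typically 0.3-1 s).
#' @param amp Burst amplitude as a multiple of each target channel's
#'   standard deviation. `amp = 0` leaves the recording unchanged.
#' @param channels Channel labels to hit; `NULL` picks a random majority
#'   subset of the montage (body-movement and cable interferences hit
#'   most electrodes at once).
#' @return The modified `mi_simulation`.
#' @export
inject_burst <- function(sim, trial_idx, t0 = 2, dur = 0.5, amp = 10,
                         channels = NULL) {
  stopifnot(inherits(sim, "mi_simulation"))
  rec <- sim$recording
  fs <- rec$fs
  L <- round(sim$config$trial_s * fs)
  n_trials <- nrow(rec$events)
  if (trial_idx < 1 || trial_idx > n_trials)
    stop("trial_idx out of range (1..", n_trials, ")")
  if (t0 < 0 || t0 + dur > sim$config$trial_s)
    stop("burst window must lie inside the trial")
  if (is.null(channels)) {
    n_hit <- max(3L, ceiling(2 * nrow(rec$samples) / 3))
    channels <- sample(rec$channel_labels, n_hit)
  }
  ch <- match(channels, rec$channel_labels)
  if (anyNA(ch)) stop("unknown channel(s): ",
                      paste(channels[is.na(ch)], collapse = ", "))
  n <- round(dur * fs)
  taper <- tukey_window(n, 0.5)
  start <- (trial_idx - 1L) * L + round(t0 * fs) + 1L
  idx <- start:(start + n - 1L)
  for (c0 in ch) {
    sd_c <- stats::sd(rec$samples[c0, ])
    rec$samples[c0, idx] <- rec$samples[c0, idx] +
      amp * sd_c * stats::rnorm(n) * taper
  }
  if (amp > 0)
    sim$truth$artifact_trials <-
      sort(unique(c(sim$truth$artifact_trials, as.integer(trial_idx))))
  sim$recording <- rec
  sim
}

tukey_window <- function(n, alpha = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Ground-truth oracle detection filters
#'
#' The rows of `solve(A_true)` corresponding to the C3-, Cz- and
#' C4-dominant sources, packaged as a detection-filter set. Each row is
#' rescaled so its recovered source has unit variance over the
#' mu/beta-band (8-30 Hz) recording — the same amplitude normalization a
#' fitted model receives, applied on the same band the fits see — so the
#' minimum-variance classification rule compares sources on a common
#' baseline. Useful as an upper-bound reference when evaluating fitted
#' filters on simulated data.
#'
#' @param sim An `mi_simulation`.
#' @param band Band (Hz) on which the unit-variance normalization is
#'   computed; default the 8-30 Hz band ICA is fitted on.
#' @return A `detection_filters` object (see [detection_filters]).
#' @export
oracle_filters <- function(sim, band = c(8, 30)) {
  stopifnot(inherits(sim, "mi_simulation"))
  W <- solve(sim$truth$A_true)
  recf <- bandpass_filter(sim$recording, band[1], band[2])
  U <- W %*% recf$samples
  W <- W / apply(U, 1L, stats::sd)
  r <- sim$truth$source_roles
  detection_filters(w_l = W[r["C3"], ], w_f = W[r["Cz"], ],
                    w_r = W[r["C4"], ],
                    channel_labels = sim$recording$channel_labels,
                    origin = NA_integer_)
}
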