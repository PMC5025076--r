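fs <- 250

make_sine_rec <- function(freqs, amps = rep(1, length(freqs)), dur = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  eeg_recording(matrix(x, 1), fs, "Cz")
}

mid_rms <- function(rec) {
  n <- ncol(rec$samples)
  sqrt(mean(rec$samples[1, (n %/% 4):(3 * n %/% 4)]^2))
}

test_that("band-pass response preserves the passband and kills the stopband", {
  b <- mibci:::design_bandpass(fs, 8, 30)
  resp <- mibci:::fir_response(b, c(4, 12, 41), fs)
  expect_lt(abs(resp[2] - 1), 0.05)       # 12 Hz within 5 %
  expect_lt(resp[1], 10^(-40 / 20))       # 4 Hz (= low/2) down >= 40 dB
  expect_lt(resp[3], 10^(-40 / 20))       # 41 Hz (= high + bw/2)
  pass <- mibci:::fir_response(b, seq(9.5, 28.5, by = 0.5), fs)
  expect_true(all(abs(20 * log10(pass)) < 1))

  # and on an actual signal
  r12 <- make_sine_rec(12)
  expect_lt(abs(mid_rms(bandpass_filter(r12, 8, 30)) / mid_rms(r12) - 1),
            0.05)
  r4 <- make_sine_rec(4)
  expect_lt(mid_rms(bandpass_filter(r4, 8, 30)) / mid_rms(r4), 10^(-40 / 20))
})

test_that("filtering is zero-phase: cross-correlation peaks at lag 0", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(4 * fs), 1), fs, "Cz")
  out <- bandpass_filter(rec, 8, 30)
  cc <- stats::ccf(drop(out$samples), drop(rec$samples), lag.max = 25,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear", {
  set.seed(2)
  x <- matrix(rnorm(2 * fs), 1); y <- matrix(rnorm(2 * fs), 1)
  f <- function(m) bandpass_filter(eeg_recording(m, fs, "Cz"), 8, 30)$samples
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-10)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- make_sine_rec(12)
  expect_error(bandpass_filter(rec, 8, 130), "Nyquist|band edges")
  expect_error(bandpass_filter(rec, -1, 30), "band edges")
  expect_error(notch_filter(rec, 200), "Nyquist")
})

test_that("notch filter suppresses 50 Hz and spares the neighborhood", {
  b <- mibci:::design_bandstop(fs, 49, 51, trans = 1)
  resp <- mibci:::fir_response(b, c(50, 45, 55, 12), fs)
  expect_lt(resp[1], 10^(-30 / 20))                  # >= 30 dB at 50 Hz
  expect_true(all(abs(20 * log10(resp[2:3])) < 1))   # < 1 dB at 45/55
  expect_lt(abs(resp[4] - 1), 0.05)                  # 12 Hz intact

  r50 <- make_sine_rec(50)
  expect_lt(mid_rms(notch_filter(r50, 50)) / mid_rms(r50), 10^(-30 / 20))
  zero <- eeg_recording(matrix(0, 2, fs), fs, c("C3", "C4"))
  expect_equal(notch_filter(zero, 50)$samples, zero$samples)
})

test_that("channel selection is a pure row permutation preserving metadata", {
  set.seed(3)
  labs14 <- c("FP1", "FP2", "F3", "F4", "FC3", "FCz", "FC4", "C3", "Cz",
              "C4", "CP3", "CPz", "CP4", "Pz")
  rec <- eeg_recording(matrix(rnorm(14 * 100), 14), fs, labs14,
                       data.frame(onset = 10L, label = 2L))
  nine <- select_channels(rec, channel_scheme("nine"))
  expect_identical(nine$channel_labels,
                   c("FC3", "FCz", "FC4", "C3", "Cz", "C4",
                     "CP3", "CPz", "CP4"))
  for (ch in nine$channel_labels)
    expect_identical(nine$samples[match(ch, nine$channel_labels), ],
                     rec$samples[match(ch, labs14), ])
  expect_identical(nine$events, rec$events)

  same <- select_channels(rec, channel_scheme(labs14))
  expect_identical(same$samples, rec$samples)
  expect_error(select_channels(rec, channel_scheme(c("C3", "XX"))),
               "not found.*XX")
})

test_that("epoching produces the stated trial lengths and labels", {
  set.seed(4)
  n_tr <- 3
  rec <- eeg_recording(matrix(rnorm(2 * n_tr * 10 * fs), 2), fs,
                       c("C3", "C4"),
                       data.frame(onset = (0:(n_tr - 1)) * 10 * fs + 1,
                                  label = c(1, 2, 3)))
  ts <- epoch_trials(rec, c(0.5, 5))
  expect_equal(ncol(ts$trials[[1]]), 1125)   # (5 - 0.5) * 250
  expect_length(ts, n_tr)
  expect_equal(ts$labels, c(1L, 2L, 3L))

  full <- epoch_trials(rec, c(0, 10))
  expect_equal(ncol(full$trials[[1]]), 2500)

  none <- eeg_recording(matrix(rnorm(2 * 100), 2), fs, c("C3", "C4"))
  expect_length(epoch_trials(none, c(0, 0.2)), 0)
})

test_that("epoching contiguous windows reproduces the recording exactly", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), fs, c("C3", "C4"),
                       data.frame(onset = c(1L, 251L, 501L, 751L),
                                  label = c(1L, 2L, 3L, 1L)))
  ts <- epoch_trials(rec, c(0, 1))
  expect_identical(do.call(cbind, ts$trials), rec$samples)
})

test_that("recording invariants are enforced", {
  expect_error(eeg_recording(matrix(0, 2, 10), fs, "C3"),
               "channel_labels")
  expect_error(eeg_recording(matrix(0, 2, 10), fs, c("C3", "C4"),
                             data.frame(onset = c(5, 2), label = c(1, 1))),
               "increasing")
  expect_error(eeg_recording(matrix(0, 2, 10), fs, c("C3", "C4"),
                             data.frame(onset = 2, label = 7)),
               "labels")
})
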