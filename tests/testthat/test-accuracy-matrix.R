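test_that("segment count follows the rounding formula", {
  expect_equal(segment_count(segmentation_params(11, 5, 4.5)), 13L)
  expect_equal(segment_count(segmentation_params(10, 10, 0)), 1L)
  # 9 / 2 = 4.5 rounds half away from zero -> 5
  expect_equal(segment_count(segmentation_params(10, 3, 1)), 5L)
  expect_error(segmentation_params(10, 3, 3), "T_o < T_s")
  expect_error(segmentation_params(10, 12, 0), "T_s <= T_t")
})

test_that("segments start at multiples of the stride", {
  fs <- 250
  x <- matrix(seq_len(2 * 11 * fs), 2, byrow = TRUE)
  p <- segmentation_params(11, 5, 4.5)
  segs <- segment_trial(x, p, fs)
  expect_length(segs, 13)
  starts_s <- seq(0, by = 0.5, length.out = 13)
  for (i in seq_along(segs)) {
    expect_equal(ncol(segs[[i]]), 1250)
    i0 <- round(starts_s[i] * fs)
    expect_identical(segs[[i]], x[, (i0 + 1):(i0 + 1250)])
  }

  p1 <- segmentation_params(10, 10, 0)
  x1 <- matrix(rnorm(2 * 10 * fs), 2)
  expect_identical(segment_trial(x1, p1, fs)[[1]], x1)
})

test_that("an overrunning last segment is truncated and zero-padded", {
  fs <- 10
  x <- matrix(rnorm(100), 1)           # 10 s at 10 Hz
  p <- segmentation_params(10, 3, 1)   # 5 segments, last spans 8-11 s
  expect_warning(segs <- segment_trial(x, p, fs), "truncated")
  expect_length(segs, 5)
  last <- segs[[5]]
  expect_equal(ncol(last), 30)
  expect_identical(last[, 1:20], x[, 81:100])
  expect_true(all(last[, 21:30] == 0))
})

test_that("stride-sized prefixes of successive segments tile the trial", {
  fs <- 250
  x <- matrix(rnorm(11 * fs), 1)
  p <- segmentation_params(11, 5, 4.5)
  segs <- segment_trial(x, p, fs)
  stride <- round((p$T_s - p$T_o) * fs)
  tiled <- do.call(cbind, lapply(segs, function(s) s[, 1:stride,
                                                     drop = FALSE]))
  expect_identical(tiled, x[, seq_len(ncol(tiled)), drop = FALSE])
})

am_sim <- generate_dataset(sim_config(n_trials_per_class = 2, trial_s = 11,
                                      seed = 77))
am_trials <- preprocess_recording(am_sim$recording,
                                  run_config(epoch_window = c(0, 11)))

test_that("accuracy matrix has the shape law M x L and [0,1]/-1 entries", {
  p <- segmentation_params(11, 5.5, 0)   # 2 segments, cheap
  am <- build_accuracy_matrix(am_trials, am_trials, p,
                              band = c(10, 14), window = c(0.5, 5),
                              cfg = fast_ica)
  expect_s3_class(am, "accuracy_matrix")
  expect_equal(dim(am$values), c(segment_count(p), length(am_trials)))
  expect_true(all(am$values == -1 | (am$values >= 0 & am$values <= 1)))
  td <- tidy(am)
  expect_equal(nrow(td), 2 * 6)
})

test_that("a single full-length segment reduces to the plain self-test", {
  one <- mibci:::subset_trials(am_trials, 1L)
  p <- segmentation_params(11, 11, 0)
  cfg1 <- ica_config(max_iter = 128, seed = 4)
  am <- build_accuracy_matrix(one, am_trials, p, band = c(10, 14),
                              window = c(0.5, 5), cfg = cfg1)
  expect_equal(dim(am$values), c(1L, 1L))
  m <- fit_ica(one$trials[[1]], cfg1, channel_labels = one$channel_labels)
  asg <- match_mrics(m$A, one$channel_labels)
  direct <- if (asg$matched)
    evaluate_filters(mibci:::filters_from_model(m, asg),
                     mibci:::prepare_class_data(am_trials, c(10, 14),
                                                c(0.5, 5)))
  else -1
  expect_equal(am$values[1, 1], direct)
})

test_that("accuracy matrices are deterministic under a fixed seed", {
  p <- segmentation_params(11, 5.5, 0)
  cfg1 <- ica_config(max_iter = 64, seed = 12)
  two <- mibci:::subset_trials(am_trials, 1:3)
  am1 <- build_accuracy_matrix(two, two, p, c(10, 14), c(0.5, 5), cfg1)
  am2 <- build_accuracy_matrix(two, two, p, c(10, 14), c(0.5, 5), cfg1)
  expect_identical(am1$values, am2$values)
})

test_that("row summaries are five-number, sentinel-aware", {
  am <- structure(list(values = matrix(0.8, 3, 4),
                       params = segmentation_params(10, 5, 0),
                       train_id = "a", test_id = "a"),
                  class = "accuracy_matrix")
  s <- summarize_rows(am)
  expect_equal(nrow(s), 3)
  expect_true(all(s$min == 0.8 & s$q1 == 0.8 & s$median == 0.8 &
                    s$q3 == 0.8 & s$max == 0.8))

  am$values <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5),
                     c(-1, -1, -1, -1, -1),
                     c(0.5, -1, 0.7, -1, 0.9))[, 1:5]
  am$values <- am$values[, 1:5]
  expect_warning(s2 <- summarize_rows(am), "no valid cells")
  expect_equal(nrow(s2), 2)
  q <- stats::quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), c(.25, .5, .75),
                       names = FALSE)
  expect_equal(s2$median[1], q[2])
  expect_equal(s2$q1[1], q[1])
  expect_equal(s2$q3[1], q[3])
  expect_equal(s2$n_valid[2], 3)
})
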