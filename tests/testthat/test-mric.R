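# nine-channel order: FC3 FCz FC4 C3 Cz C4 CP3 CPz CP4
#                      1   2   3   4  5  6  7   8   9

test_that("MRIC matching finds the columns peaking at C3, Cz, C4", {
  A <- diag(0.2, 9)
  A[5, 2] <- 1     # column 2 peaks at Cz
  A[4, 4] <- 1     # column 4 peaks at C3
  A[6, 8] <- -1.5  # column 8 peaks (in magnitude) at C4
  asg <- match_mrics(A, nine_labels)
  expect_true(asg$matched)
  expect_equal(c(asg$ic_C3, asg$ic_Cz, asg$ic_C4), c(4L, 2L, 8L))
})

test_that("identity mixing matches the C3/Cz/C4 basis columns", {
  asg <- match_mrics(diag(9), nine_labels)
  expect_true(asg$matched)
  expect_equal(c(asg$ic_C3, asg$ic_Cz, asg$ic_C4), c(4L, 5L, 6L))
})

test_that("no candidate for a target channel means a bad trial", {
  A <- matrix(0.1, 9, 9)
  A[2, ] <- 1    # every column peaks at FCz
  expect_false(match_mrics(A, nine_labels)$matched)
  expect_error(match_mrics(diag(3), c("FC3", "FCz", "FC4")),
               "C3.*Cz.*C4|contain")
})

test_that("ties go to the candidate with the larger projection", {
  A <- diag(0.2, 9)
  A[4, 1] <- 0.8   # both columns 1 and 2 peak at C3
  A[4, 2] <- 1.1
  A[5, 5] <- 1; A[6, 6] <- 1
  asg <- match_mrics(A, nine_labels)
  expect_true(asg$matched)
  expect_equal(asg$ic_C3, 2L)
})

make_basis_filters <- function() {
  detection_filters(w_l = c(1, 0, 0), w_f = c(0, 1, 0), w_r = c(0, 0, 1),
                    channel_labels = c("C3", "Cz", "C4"))
}

sine_trial <- function(amps, fs = 250, dur = 10, freq = 12) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  rbind(amps[1] * sin(2 * pi * freq * t),
        amps[2] * sin(2 * pi * freq * t + 1),
        amps[3] * sin(2 * pi * freq * t + 2))
}

test_that("minimum-variance rule assigns the contralateral class", {
  f <- make_basis_filters()
  # var(u_l), var(u_r), var(u_f) = (0.5, 1.2, 0.9): min is u_l -> class 2
  x <- sine_trial(c(sqrt(2 * 0.5), sqrt(2 * 0.9), sqrt(2 * 1.2)))
  expect_equal(classify_trial(f, x, c(10, 14), c(0.5, 5), 250), 2L)
  # min var(u_r) -> class 1; min var(u_f) -> class 3
  x1 <- sine_trial(c(2, 2, 1))
  expect_equal(classify_trial(f, x1, c(10, 14), c(0.5, 5), 250), 1L)
  x3 <- sine_trial(c(2, 1, 2))
  expect_equal(classify_trial(f, x3, c(10, 14), c(0.5, 5), 250), 3L)
})

test_that("exact variance ties resolve in rule order (class 1 first)", {
  f <- make_basis_filters()
  t <- seq(0, 10 - 1 / 250, by = 1 / 250)
  s <- sin(2 * pi * 12 * t)
  x <- rbind(s, s, s)          # identical channels: all variances equal
  expect_equal(classify_trial(f, x, c(10, 14), c(0.5, 5), 250), 1L)
})

test_that("classification is deterministic and scale invariant", {
  f <- make_basis_filters()
  x <- sine_trial(c(1.2, 0.7, 1.9))
  l1 <- classify_trial(f, x, c(10, 14), c(0.5, 5), 250)
  expect_identical(l1, classify_trial(f, x, c(10, 14), c(0.5, 5), 250))
  expect_identical(l1, classify_trial(f, 37.5 * x, c(10, 14), c(0.5, 5), 250))
})

test_that("oracle filters classify a clean synthetic run almost perfectly", {
  acc <- evaluate_filters(oracle_filters(fix_sim), fix_trials,
                          c(10, 14), c(0.5, 5))
  expect_gte(acc, 0.9)
})

test_that("random filters sit at chance on a balanced set", {
  cd <- mibci:::prepare_class_data(fix_trials, c(10, 14), c(0.5, 5))
  set.seed(11)
  accs <- vapply(1:200, function(i) {
    w <- matrix(rnorm(27), 3)
    f <- detection_filters(w[1, ], w[2, ], w[3, ],
                           channel_labels = fix_trials$channel_labels)
    evaluate_filters(f, cd)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.06)
})

test_that("a degenerate always-right classifier scores 1", {
  f <- make_basis_filters()
  x1 <- sine_trial(c(2, 2, 1))   # classified 1
  ts <- trial_set(list(x1, x1, x1), labels = c(1, 1, 1), fs = 250,
                  channel_labels = c("C3", "Cz", "C4"))
  expect_equal(evaluate_filters(f, ts, c(10, 14), c(0.5, 5)), 1)
})

test_that("first round labels most clean trials good with valid filters", {
  fr <- first_round_select(fix_trials, fast_ica)
  expect_gte(fr$report$P, 9)      # 12 clean trials
  good <- fr$report$data$round1_good
  expect_identical(!vapply(fr$filters, is.null, TRUE), good)
  for (f in fr$filters[good]) {
    expect_s3_class(f, "detection_filters")
    expect_true(all(is.finite(f$w)))
  }
  # round-1 bad trials carry zero accuracy
  expect_true(all(fr$report$data$R_j[!good] == 0))
})

test_that("second-round threshold is the mean of nonzero accuracies", {
  rep0 <- selection_report(1:5, c(1, 2, 3, 1, 2),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE))
  rep0$data$R_j <- c(0.9, 0.8, 0.4, 0, 0)
  out <- second_round_select(rep0)
  expect_equal(out$threshold, 0.7)
  expect_equal(out$data$trial_index[out$data$kept], c(1L, 2L))

  # all equal accuracies: everything kept
  rep1 <- selection_report(1:3, c(1, 2, 3), rep(TRUE, 3))
  rep1$data$R_j <- rep(0.6, 3)
  expect_equal(sum(second_round_select(rep1)$data$kept), 3)

  rep2 <- selection_report(1:2, c(1, 2), c(FALSE, FALSE))
  expect_error(second_round_select(rep2), "no good trials")
})

test_that("the 75-trial worked example: P = 66, mean 0.806, 31 kept", {
  good <- rep(c(TRUE, FALSE), c(66, 9))
  rep0 <- selection_report(1:75, rep(1:3, 25), good)
  r_low <- rep(0.70, 35)
  r_high <- rep((0.806 * 66 - sum(r_low)) / 31, 31)
  rep0$data$R_j[good] <- c(r_low, r_high)
  expect_equal(rep0$P, 66)
  out <- second_round_select(rep0)
  expect_equal(out$threshold, 0.806, tolerance = 1e-12)
  expect_equal(sum(out$data$R_j[out$data$round1_good] < out$threshold), 35)
  expect_equal(sum(out$data$kept), 31)
})

test_that("ICA-T concatenates the top-m kept trials", {
  sel <- two_round_selection(fix_trials, fix_cfg)
  res <- build_ica_t(fix_trials, sel$report, m = 3, fast_ica)
  expect_s3_class(res$filters, "detection_filters")
  expect_length(res$filters$origin, 3)
  d <- res$report$data
  expect_equal(sum(d$in_top_m), 3)
  expect_true(all(d$kept[d$in_top_m]))           # top-m drawn from kept
  # top-m are the kept trials with the highest accuracies
  expect_equal(sort(d$R_j[d$in_top_m]),
               sort(d$R_j[d$kept], decreasing = TRUE)[3:1])
  expect_warning(build_ica_t(fix_trials, sel$report, m = 99, fast_ica),
                 "kept trials")
})

test_that("top-m selection never reaches outside the kept set", {
  rep0 <- selection_report(1:8, rep(1:2, 4), rep(TRUE, 8))
  rep0$data$R_j <- c(0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.3, 0.2)
  rep0 <- second_round_select(rep0, rule = "absolute", value = 0.6)
  top1 <- mibci:::top_m_trials(rep0, 4)
  expect_true(all(top1 %in% rep0$data$trial_index[rep0$data$kept]))
  # drop one kept trial: the refilled slot still comes from the kept set
  rep0$data$kept[rep0$data$trial_index == top1[1]] <- FALSE
  top2 <- mibci:::top_m_trials(rep0, 4)
  expect_false(top1[1] %in% top2)
  expect_true(all(top2 %in% rep0$data$trial_index[rep0$data$kept]))
})

test_that("ties in top-m order break by ascending trial index", {
  rep0 <- selection_report(1:4, rep(1, 4), rep(TRUE, 4))
  rep0$data$R_j <- c(0.8, 0.9, 0.8, 0.9)
  rep0 <- second_round_select(rep0, rule = "absolute", value = 0)
  expect_equal(mibci:::top_m_trials(rep0, 3), c(2L, 4L, 1L))
})

test_that("sliding-window builder yields n - win + 1 filter sets", {
  flt <- build_ica_s(fix_trials, win = 10, step = 1, fast_ica)
  expect_length(flt, 3)     # 12 trials, win 10
  cd <- mibci:::prepare_class_data(fix_trials, c(10, 14), c(0.5, 5))
  for (f in flt)
    if (!is.null(f)) expect_gte(evaluate_filters(f, cd), 1 / 3)
  expect_error(build_ica_s(fix_trials, win = 0), "positive")
})

test_that("one full-length window equals fitting on all trials", {
  ten <- mibci:::subset_trials(fix_trials, 1:10)
  cfg1 <- ica_config(max_iter = 128, seed = 5)
  flt <- build_ica_s(ten, win = 10, step = 1, cfg1)
  expect_length(flt, 1)
  X <- do.call(cbind, ten$trials)
  m <- fit_ica(X, cfg1, channel_labels = ten$channel_labels)
  asg <- match_mrics(m$A, ten$channel_labels)
  direct <- mibci:::filters_from_model(m, asg)
  expect_equal(flt[[1]]$w, direct$w, tolerance = 1e-12)
})

test_that("affected windows cover exactly the ranges touching artifacts", {
  expect_equal(affected_windows(c(43, 46), 75, 10, 1), 34:46)
  expect_equal(affected_windows(1, 75, 10, 1), 1L)
  expect_equal(affected_windows(75, 75, 10, 1), 66L)
  expect_error(affected_windows(80, 75, 10, 1), "1..n_trials")
})
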