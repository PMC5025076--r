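random_spd <- function(n) {
  M <- matrix(rnorm(n * n), n)
  crossprod(M) / n + diag(0.05, n)
}

test_that("class covariance averages trace-normalized trial covariances", {
  set.seed(1)
  x <- matrix(rnorm(2 * 50000), 2)
  C <- class_covariance(list(x))
  expect_equal(C, diag(0.5, 2), tolerance = 0.02)
  expect_equal(sum(diag(C)), 1, tolerance = 1e-12)

  set.seed(2)
  trials <- replicate(3, matrix(rnorm(3 * 500), 3), simplify = FALSE)
  expect_equal(class_covariance(c(trials, trials)),
               class_covariance(trials), tolerance = 1e-12)

  flat <- rbind(rep(1, 100), rnorm(100))
  expect_warning(class_covariance(list(flat)), "rank deficient|constant")
  expect_error(class_covariance(list()), "empty")
})

test_that("already-diagonal covariances give basis filters", {
  pr <- mibci:::csp_from_cov(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(unname(pr$eigvals), c(0.8, 0.2), tolerance = 1e-12)
  # filters are the standard basis up to sign/scale
  f <- abs(pr$filters / apply(abs(pr$filters), 1, max))
  expect_equal(f, rbind(c(1, 0), c(0, 1)), tolerance = 1e-9)

  same <- mibci:::csp_from_cov(diag(2) * 0.5, diag(2) * 0.5)
  expect_equal(unname(same$eigvals), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("joint-diagonalization identities hold on random SPD pairs", {
  set.seed(3)
  for (i in 1:10) {
    S1 <- random_spd(4); S2 <- random_spd(4)
    pr <- mibci:::csp_from_cov(S1, S2)
    W <- pr$W_full
    D1 <- t(W) %*% S1 %*% W
    D2 <- t(W) %*% S2 %*% W
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-6)
    expect_equal(D1 + D2, diag(4), tolerance = 1e-6)
    expect_true(all(diff(diag(D1)) <= 1e-12))    # descending eigenvalues
    expect_true(all(pr$eigvals >= -1e-9 & pr$eigvals <= 1 + 1e-9))
  }
})

test_that("swapping class roles mirrors the eigenvalues and filter roles", {
  set.seed(4)
  S1 <- random_spd(3); S2 <- random_spd(3)
  a <- mibci:::csp_from_cov(S1, S2)
  b <- mibci:::csp_from_cov(S2, S1)
  expect_equal(unname(a$eigvals), unname(1 - b$eigvals[2:1]),
               tolerance = 1e-9)
  align <- function(v) v / v[which.max(abs(v))]
  expect_equal(align(a$filters[1, ]), align(b$filters[2, ]),
               tolerance = 1e-6)
})

test_that("rank-deficient composite covariance is refused", {
  x <- matrix(rnorm(100), 1)
  dup <- rbind(x, x)
  expect_error(suppressWarnings(compute_csp_pair(list(dup), list(dup))),
               "rank deficient")
})

csp_fix_trials <- mibci:::epoch_window_trials(fix_trials, c(0.5, 5))

test_that("OVR model keeps exactly six spatial filters and separates", {
  model <- fit_csp_ovr(csp_fix_trials)
  expect_length(model$splits, 3)
  n_filters <- sum(vapply(model$splits,
                          function(s) nrow(s$pair$filters), 0L))
  expect_equal(n_filters, 6L)
  td <- tidy(model)
  expect_equal(nrow(td), 6)

  pred <- vapply(csp_fix_trials$trials,
                 function(x) classify_csp(model, x), 0)
  expect_gte(mean(pred == csp_fix_trials$labels), 0.8)

  two_cls <- mibci:::subset_trials(csp_fix_trials,
                                   which(csp_fix_trials$labels != 3))
  expect_error(fit_csp_ovr(two_cls), "three classes")
})

test_that("CSP labels are invariant under common positive scaling", {
  model <- fit_csp_ovr(csp_fix_trials)
  scaled <- lapply(csp_fix_trials$trials, function(x) 12.5 * x)
  p1 <- vapply(csp_fix_trials$trials, function(x) classify_csp(model, x), 0)
  p2 <- vapply(scaled, function(x) classify_csp(model, x), 0)
  expect_identical(p1, p2)
  # filters from scaled data span the same directions
  scaled_ts <- trial_set(scaled, csp_fix_trials$labels, csp_fix_trials$fs,
                         csp_fix_trials$channel_labels)
  m2 <- fit_csp_ovr(scaled_ts)
  for (k in 1:3) {
    f1 <- model$splits[[k]]$pair$filters
    f2 <- m2$splits[[k]]$pair$filters
    for (r in 1:2) {
      c12 <- abs(sum(f1[r, ] * f2[r, ])) /
        sqrt(sum(f1[r, ]^2) * sum(f2[r, ]^2))
      expect_gt(c12, 1 - 1e-9)
    }
  }
})

test_that("the stored linear discriminant reproduces MASS::lda decisions", {
  model <- fit_csp_ovr(csp_fix_trials)
  for (s in model$splits) {
    feats <- t(vapply(csp_fix_trials$trials, function(x)
      mibci:::csp_features(s$pair$filters, x), numeric(2)))
    grp <- factor(csp_fix_trials$labels == s$pair$class_pair[1],
                  levels = c(FALSE, TRUE))
    lda <- MASS::lda(feats, grouping = grp)
    ref <- stats::predict(lda, feats)$posterior[, "TRUE"] > 0.5
    mine <- apply(feats, 1, function(f)
      with(s$disc, d * sum(a * (f - m)) + logit0) > 0)
    expect_equal(unname(mine), unname(ref))
  }
})

test_that("randomized self-test is seeded, sized and degenerate-safe", {
  st1 <- csp_self_test(csp_fix_trials, frac = 0.8, repeats = 5, seed = 9)
  st2 <- csp_self_test(csp_fix_trials, frac = 0.8, repeats = 5, seed = 9)
  expect_identical(st1, st2)
  expect_equal(nrow(st1), 5)
  expect_gte(attr(st1, "mean"), 0.6)

  stf <- csp_self_test(csp_fix_trials, frac = 1, repeats = 3, seed = 1)
  expect_equal(attr(stf, "sd"), 0)
})
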