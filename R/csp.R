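# One-versus-rest common spatial patterns baseline with voting.

#' Class-average covariance
#'
#' Average over trials of the per-trial channel covariance, each trial's
#' covariance normalized by its trace (standard CSP practice so that
#' high-power trials do not dominate). Channels are centered per trial.
#'
#' @param trials List of channels-by-samples matrices of one class.
#' @return Symmetric positive semidefinite covariance matrix.
#' @export
class_covariance <- function(trials) {
  if (!length(trials)) stop("empty class: no trials")
  covs <- lapply(trials, function(x) {
    x <- x - rowMeans(x)
    C <- tcrossprod(x) / ncol(x)
    if (any(diag(C) <= .Machine$double.eps))
      warning("constant channel: covariance is rank deficient")
    C / sum(diag(C))
  })
  Reduce(`+`, covs) / length(covs)
}

#' Two-class CSP filter pair
#'
#' Solves the joint diagonalization of the two class covariances: finds W
#' with `t(W) %*% S1 %*% W` diagonal and
#' `t(W) %*% (S1 + S2) %*% W == I`, and keeps the two filters of maximum
#' and minimum eigenvalue — the directions with the most extreme
#' between-class variance ratio.
#'
#' @param X1,X2 Lists of trials (channels x samples) for the two classes.
#' @return An object of class `csp_pair`: `filters` (2 x N), `eigvals`
#'   (lambda_max, lambda_min), `W_full`, `class_pair`.
#' @export
compute_csp_pair <- function(X1, X2) {
  S1 <- class_covariance(X1)
  S2 <- class_covariance(X2)
  csp_from_cov(S1, S2)
}

# Generalized eigenproblem S1 v = lambda (S1 + S2) v via whitening of the
# composite covariance.
csp_from_cov <- function(S1, S2, class_pair = c(1L, 0L)) {
  Sc <- S1 + S2
  e <- eigen(Sc, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values))
    stop("composite covariance is rank deficient; check for constant ",
         "or duplicated channels")
  P <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  es <- eigen(P %*% S1 %*% P, symmetric = TRUE)
  W_full <- P %*% es$vectors            # columns jointly diagonalize S1, S2
  lam <- es$values
  filters <- t(W_full[, c(1L, length(lam)), drop = FALSE])
  structure(list(filters = filters,
                 eigvals = c(lambda_max = lam[1],
                             lambda_min = lam[length(lam)]),
                 W_full = W_full, class_pair = class_pair),
            class = "csp_pair")
}

#' @export
print.csp_pair <- function(x, ...) {
  cat(sprintf("<csp_pair> class %s vs rest; lambda = (%.3f, %.3f)\n",
              x$class_pair[1], x$eigvals[1], x$eigvals[2]))
  invisible(x)
}

# normalized log-variance features: scale invariant (a common positive
# rescaling of the trial cancels in v / sum(v))
csp_features <- function(filters, x) {
  x <- x - rowMeans(x)
  u <- filters %*% x
  v <- apply(u, 1L, stats::var)
  log(v / sum(v))
}

#' Fit the one-versus-rest CSP model
#'
#' For each class, computes the CSP pair of that class against the pooled
#' other two, then fits a linear discriminant (on the log-variances of the
#' two filtered signals) separating the class from the rest. Three splits
#' times a max/min filter pair gives the six retained spatial filters.
#'
#' @param trials A [trial_set] containing all three classes.
#' @return An object of class `csp_ovr`: list of three `csp_pair`s and
#'   per-split LDA discriminants.
#' @export
fit_csp_ovr <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  present <- sort(unique(trials$labels))
  if (!identical(present, 1:3))
    stop("all three classes must be present (got ",
         paste(present, collapse = ","), ")")
  splits <- lapply(1:3, function(cls) {
    X1 <- trials$trials[trials$labels == cls]
    X2 <- trials$trials[trials$labels != cls]
    pair <- compute_csp_pair(X1, X2)
    pair$class_pair <- c(cls, 0L)
    feats <- t(vapply(trials$trials, function(x)
      csp_features(pair$filters, x), numeric(2)))
    grp <- factor(trials$labels == cls, levels = c(FALSE, TRUE))
    lda <- MASS::lda(feats, grouping = grp)
    # explicit linear form of the 2-class discriminant (log posterior
    # odds up to the shared scale): score = d * a'(x - m) + log-prior-odds
    a <- unname(drop(lda$scaling[, 1]))
    m <- unname(colMeans(lda$means))
    d <- sum(a * (lda$means[2, ] - lda$means[1, ]))
    disc <- list(a = a, m = m, d = d,
                 logit0 = unname(log(lda$prior[[2]] / lda$prior[[1]])))
    list(pair = pair, disc = disc)
  })
  structure(list(splits = splits, channel_labels = trials$channel_labels),
            class = "csp_ovr")
}

#' @export
print.csp_ovr <- function(x, ...) {
  cat("<csp_ovr> 3 one-vs-rest splits, 6 spatial filters\n")
  invisible(x)
}

#' @rdname fit_csp_ovr
#' @param x A `csp_ovr` model.
#' @param ... Unused.
#' @export
tidy.csp_ovr <- function(x, ...) {
  dplyr::bind_rows(lapply(x$splits, function(s) {
    tibble::tibble(class = s$pair$class_pair[1],
                   filter = c("max", "min"),
                   lambda = as.numeric(s$pair$eigvals))
  }))
}

#' Classify a trial with the OVR-CSP model
#'
#' Each binary discriminant votes for its class or for "rest"; the label
#' is the class with a positive vote. With no vote or several, the class
#' with the largest discriminant score wins.
#'
#' @param model A `csp_ovr` from [fit_csp_ovr].
#' @param x Trial matrix (channels x samples).
#' @return Integer class label in 1:3.
#' @export
classify_csp <- function(model, x) {
  stopifnot(inherits(model, "csp_ovr"))
  scores <- vapply(model$splits, function(s) {
    feats <- csp_features(s$pair$filters, x)
    with(s$disc, d * sum(a * (feats - m)) + logit0)  # log-odds of "this class"
  }, numeric(1))
  votes <- which(scores > 0)
  if (length(votes) == 1L) votes else which.max(scores)
}

#' Randomized self-test of the CSP pipeline
#'
#' Per repeat, a stratified random fraction of trials trains the OVR-CSP
#' model; by default all trials are then tested (the usual self-testing
#' protocol for this method). `test = "holdout"` scores only the trials
#' left out of training — the unbiased variant, which is what a
#' permutation (label-shuffling) baseline should use, since testing on
#' training trials inflates accuracy well above chance even for
#' unlearnable labels.
#'
#' @param trials A [trial_set].
#' @param frac Training fraction (default 0.8, i.e. 60 of 75 trials).
#' @param repeats Number of random repeats (default 30).
#' @param seed Optional RNG seed.
#' @param test `"all"` (default) or `"holdout"`.
#' @return A tibble with one row per repeat (`repeat_id`, `accuracy`) and
#'   attributes `mean` and `sd`.
#' @export
csp_self_test <- function(trials, frac = 0.8, repeats = 30, seed = NULL,
                          test = c("all", "holdout")) {
  stopifnot(inherits(trials, "trial_set"))
  test <- match.arg(test)
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(seq_len(repeats), function(r) {
    tr_idx <- unlist(lapply(1:3, function(cls) {
      pool <- which(trials$labels == cls)
      sample(pool, max(1L, round(frac * length(pool))))
    }))
    model <- fit_csp_ovr(subset_trials(trials, sort(tr_idx)))
    te_idx <- if (test == "all") seq_along(trials$trials)
              else setdiff(seq_along(trials$trials), tr_idx)
    if (!length(te_idx)) te_idx <- seq_along(trials$trials)
    pred <- vapply(trials$trials[te_idx],
                   function(x) classify_csp(model, x), 0)
    mean(pred == trials$labels[te_idx])
  }, numeric(1))
  out <- tibble::tibble(repeat_id = seq_len(repeats), accuracy = acc)
  attr(out, "mean") <- mean(acc)
  attr(out, "sd") <- stats::sd(acc)
  out
}
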