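#' Configuration for the Infomax ICA optimizer
#'
#' Optimizer constants for [fit_ica]. The defaults are engineering choices
#' tuned for few-channel (N <= 9) EEG: a learning rate that shrinks with
#' channel count, annealing when successive natural-gradient sweep updates
#' turn by more than `anneal_deg` degrees, and stochastic block updates
#' over shuffled samples. The annealing threshold is deliberately obtuse
#' (110 degrees): per-sweep update directions are noisy, and annealing on
#' mild direction changes collapses the learning rate long before the
#' transient is over; only genuine oscillation (reversal) should slow the
#' optimizer down.
#'
#' @param learning_rate Initial step size; default `0.04 / log(n_channels)`
#'   is resolved at fit time when `NULL`.
#' @param max_iter Maximum number of sweeps through the data.
#' @param tol Convergence threshold on the largest absolute element of the
#'   per-sweep change in the separating matrix W.
#' @param block_size Samples per stochastic block.
#' @param anneal_deg Angle (degrees) between successive updates beyond which
#'   the learning rate is annealed.
#' @param anneal_factor Multiplicative learning-rate decay on annealing.
#' @param seed Optional integer seed applied before fitting (block shuffling
#'   is the only stochastic element). `NULL` leaves the RNG state alone.
#' @return An object of class `ica_config`.
#' @export
ica_config <- function(learning_rate = NULL, max_iter = 512, tol = 1e-7,
                       block_size = 256, anneal_deg = 110,
                       anneal_factor = 0.9, seed = NULL) {
  if (!is.null(learning_rate) && learning_rate <= 0)
    stop("learning_rate must be positive")
  if (max_iter < 1 || block_size < 1) stop("max_iter and block_size must be >= 1")
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  structure(list(learning_rate = learning_rate, max_iter = as.integer(max_iter),
                 tol = tol, block_size = as.integer(block_size),
                 anneal_deg = anneal_deg, anneal_factor = anneal_factor,
                 seed = seed),
            class = "ica_config")
}

#' Fit Infomax ICA to multichannel data
#'
#' Estimates a square separating matrix W by information maximization with
#' natural-gradient updates,
#' `W <- W + lr * (I - E[K tanh(u) u' + u u']) W`,
#' where the diagonal switch matrix K carries the sign of each source's
#' kurtosis (+1 super-Gaussian, -1 sub-Gaussian), re-estimated every sweep.
#' W is initialized as `0.1 * I`; channels are centered but not whitened
#' (the natural gradient does not require whitening). After fitting, the
#' model is normalized to unit source variance ([normalize_model]) and each
#' pattern/filter pair is sign-flipped so the largest-magnitude entry of
#' every mixing-matrix column is positive, removing ICA's sign
#' indeterminacy before topography matching.
#'
#' If W degenerates during iteration the fit restarts with half the
#' learning rate (up to 3 restarts, with a warning) before failing.
#'
#' @param data Numeric matrix, channels x samples. Short data segments
#'   (fewer than `20 * n_channels` samples) are rejected.
#' @param cfg An [ica_config].
#' @param channel_labels Optional channel names attached to the model.
#' @return An object of class `mixing_model` with elements `A` (mixing
#'   matrix; columns are spatial patterns), `W` (separating matrix; rows are
#'   spatial filters), `U` (unit-variance sources), `channel_labels`,
#'   `converged`, `n_iter`.
#' @export
#' @examples
#' set.seed(1)
#' S <- matrix(rnorm(2 * 2000) * rexp(2 * 2000), 2)   # super-Gaussian
#' X <- matrix(c(1, .5, .5, 1), 2) %*% S
#' m <- fit_ica(X, ica_config(max_iter = 200))
#' m$converged
fit_ica <- function(data, cfg = ica_config(), channel_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("data contains non-finite values")
  N <- nrow(data); T <- ncol(data)
  if (T < 20 * N)
    stop("need at least 20 samples per channel to fit ICA (got ",
         T, " for ", N, " channels)")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(N))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lr <- cfg$learning_rate %||% (0.04 / log(max(N, 2)))
  Xc <- data - rowMeans(data)

  fit <- NULL
  for (attempt in 0:3) {
    W0 <- diag(0.1, N)
    res <- infomax_core(Xc, W0, lr, cfg$max_iter, cfg$tol,
                        cfg$block_size, cfg$anneal_deg, cfg$anneal_factor)
    if (!res$blowup && all(is.finite(res$W)) &&
        abs(det(res$W)) > .Machine$double.eps) {
      fit <- res
      break
    }
    lr <- lr / 2
    warning("ICA iteration degenerated; restarting with learning rate ", lr)
  }
  if (is.null(fit)) stop("ICA failed to converge after 3 restarts")

  W <- fit$W
  U <- W %*% Xc
  model <- structure(
    list(A = solve(W), W = W, U = U, channel_labels = channel_labels,
         converged = fit$converged, n_iter = fit$n_iter),
    class = "mixing_model")
  model <- normalize_model(model)
  canonicalize_signs(model)
}

#' Normalize a mixing model to unit source variance
#'
#' Removes the amplitude indeterminacy of ICA: each source row of U is
#' scaled to unit standard deviation, the corresponding column of the
#' mixing matrix A absorbs the removed scale, and W is recomputed as the
#' inverse of A so that `A %*% W` stays the identity.
#'
#' @param model A `mixing_model`.
#' @return The normalized `mixing_model`.
#' @export
normalize_model <- function(model) {
  stopifnot(inherits(model, "mixing_model"))
  s <- apply(model$U, 1L, stats::sd)
  bad <- which(s <= .Machine$double.eps)
  if (length(bad))
    stop("source(s) with zero variance: ", paste(bad, collapse = ", "))
  model$U <- model$U / s
  model$A <- model$A * rep(s, each = nrow(model$A))
  model$W <- solve(model$A)
  model
}

# Flip each (A column, W row, U row) triple so the largest-|entry| of the A
# column is positive.
canonicalize_signs <- function(model) {
  N <- ncol(model$A)
  for (j in seq_len(N)) {
    peak <- which.max(abs(model$A[, j]))
    if (model$A[peak, j] < 0) {
      model$A[, j] <- -model$A[, j]
      model$W[j, ] <- -model$W[j, ]
      model$U[j, ] <- -model$U[j, ]
    }
  }
  model
}

#' @export
print.mixing_model <- function(x, ...) {
  cat(sprintf("<mixing_model> %d sources, %d samples; %s after %d sweeps\n",
              nrow(x$U), ncol(x$U),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Apply spatial filters to a trial
#'
#' Computes `w %*% x`: each row of `w` is a spatial filter extracting one
#' source time course from the multichannel trial.
#'
#' @param w Numeric matrix of spatial-filter rows (k x N).
#' @param x Numeric trial matrix (N x T).
#' @return A k x T matrix of source time courses.
#' @export
apply_filters <- function(w, x) {
  w <- rbind(w)
  x <- as.matrix(x)
  if (ncol(w) != nrow(x))
    stop("filter length (", ncol(w), ") must match channel count (",
         nrow(x), ")")
  w %*% x
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between a product
#' `P = W %*% A_true` and a scaled permutation matrix, normalized to
#' `[0, 1]`; 0 means perfect separation.
#'
#' @param P Square numeric matrix, typically `W %*% A_true`.
#' @return A number in `[0, 1]`.
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  N <- nrow(P)
  stopifnot(N == ncol(P), N > 1)
  rows <- sum(rowSums(P) / apply(P, 1, max) - 1) / (N - 1)
  cols <- sum(colSums(P) / apply(P, 2, max) - 1) / (N - 1)
  (rows + cols) / (2 * N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
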