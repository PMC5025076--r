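# Segment-level BCI construction over consecutively overlapping windows
# and the M x L accuracy matrix used to localize artifact segments.

#' Segmentation parameters
#'
#' Trial length `T_t`, segment length `T_s` and neighbor overlap `T_o`
#' (all in seconds), with `0 <= T_o < T_s <= T_t`.
#'
#' @param T_t,T_s,T_o Seconds.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(T_t, T_s, T_o) {
  if (!(0 <= T_o && T_o < T_s && T_s <= T_t))
    stop("need 0 <= T_o < T_s <= T_t")
  structure(list(T_t = T_t, T_s = T_s, T_o = T_o),
            class = "segmentation_params")
}

# round half away from zero (R's round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Number of overlapping segments per trial
#'
#' `M = round((T_t - T_o) / (T_s - T_o))`, rounding halves away from zero.
#' With an 11 s trial, 5 s segments and 4.5 s overlap this gives 13
#' segments.
#'
#' @param p A [segmentation_params].
#' @return Integer segment count M.
#' @export
#' @examples
#' segment_count(segmentation_params(11, 5, 4.5))  # 13
segment_count <- function(p) {
  stopifnot(inherits(p, "segmentation_params"))
  stride <- p$T_s - p$T_o
  if (stride <= 0) stop("T_s must exceed T_o")
  as.integer(round_half_away((p$T_t - p$T_o) / stride))
}

#' Cut one trial into consecutively overlapping segments
#'
#' The i-th segment starts at `(i - 1) * (T_s - T_o)` seconds and has
#' `T_s * fs` samples; if the last segment runs past the trial end it is
#' truncated and zero-padded back to full length (with a warning).
#'
#' @param x Trial matrix (channels x samples), at least `T_t * fs` samples.
#' @param p A [segmentation_params].
#' @param fs Sampling rate in Hz.
#' @return List of M segment matrices.
#' @export
segment_trial <- function(x, p, fs) {
  stopifnot(inherits(p, "segmentation_params"))
  x <- as.matrix(x)
  if (ncol(x) < round(p$T_t * fs))
    stop("trial shorter than T_t at the stated sampling rate")
  M <- segment_count(p)
  n_seg <- round(p$T_s * fs)
  stride <- round((p$T_s - p$T_o) * fs)
  lapply(seq_len(M), function(i) {
    i0 <- (i - 1L) * stride
    idx <- (i0 + 1L):(i0 + n_seg)
    over <- idx > ncol(x)
    if (any(over)) {
      warning("segment ", i, " truncated at trial end; zero-padded")
      seg <- matrix(0, nrow(x), n_seg)
      seg[, !over] <- x[, idx[!over], drop = FALSE]
      seg
    } else x[, idx, drop = FALSE]
  })
}

#' Build the segment-level accuracy matrix
#'
#' For every segment i of every training trial j: fit ICA on that segment,
#' match the motor-related components, and evaluate the resulting filter
#' set over the whole test set with the zero-training classifier. Entry
#' (i, j) is that BCI's accuracy; segments where MRIC matching (or the
#' fit) fails get the sentinel -1, distinguishing "no BCI" from "a BCI
#' that always errs". Self-testing is `test = train`. Low columns localize
#' artifact trials; low cells localize artifact segments within a trial.
#'
#' @param train,test [trial_set]s (train trials at least `T_t` long).
#' @param p A [segmentation_params].
#' @param band,window Subject band (Hz) and analysis window (s) for
#'   classification.
#' @param cfg An [ica_config].
#' @return An object of class `accuracy_matrix`: `values` (M x L, in
#'   `[0, 1]` or -1), `params`, `train_id`, `test_id`.
#' @export
build_accuracy_matrix <- function(train, test = train, p, band, window,
                                  cfg = ica_config(),
                                  train_id = "train", test_id = "test") {
  stopifnot(inherits(train, "trial_set"), inherits(test, "trial_set"))
  M <- segment_count(p)
  L <- length(train)
  cd <- prepare_class_data(test, band, window)
  values <- matrix(-1, M, L)
  for (j in seq_len(L)) {
    segs <- segment_trial(train$trials[[j]], p, train$fs)
    for (i in seq_len(M)) {
      acc <- tryCatch({
        model <- fit_ica(segs[[i]], cfg,
                         channel_labels = train$channel_labels)
        asg <- match_mrics(model$A, train$channel_labels)
        if (!asg$matched) -1
        else evaluate_filters(filters_from_model(model, asg), cd)
      }, error = function(e) -1)
      values[i, j] <- acc
    }
  }
  structure(list(values = values, params = p,
                 train_id = train_id, test_id = test_id),
            class = "accuracy_matrix")
}

#' @export
print.accuracy_matrix <- function(x, ...) {
  ok <- x$values >= 0
  cat(sprintf("<accuracy_matrix> %d segments x %d trials (%s -> %s); %d/%d cells valid, mean accuracy %.3f\n",
              nrow(x$values), ncol(x$values), x$train_id, x$test_id,
              sum(ok), length(ok), mean(x$values[ok])))
  invisible(x)
}

#' @rdname build_accuracy_matrix
#' @param x An `accuracy_matrix`.
#' @param ... Unused.
#' @export
tidy.accuracy_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(segment = rep(seq_len(nrow(v)), ncol(v)),
                 trial = rep(seq_len(ncol(v)), each = nrow(v)),
                 accuracy = ifelse(as.vector(v) < 0, NA_real_, as.vector(v)))
}

#' Per-segment five-number summaries of an accuracy matrix
#'
#' Min, quartiles, median and max per matrix row (segment position across
#' trials), excluding sentinel cells. Rows with no valid cell are omitted
#' with a warning.
#'
#' @param am An `accuracy_matrix`.
#' @param type Quantile rule passed to [stats::quantile()] (default 7,
#'   R's default).
#' @return A tibble with columns `segment`, `n_valid`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
summarize_rows <- function(am, type = 7) {
  stopifnot(inherits(am, "accuracy_matrix"))
  rows <- lapply(seq_len(nrow(am$values)), function(i) {
    v <- am$values[i, ]
    v <- v[v >= 0]
    if (!length(v)) {
      warning("segment row ", i, " has no valid cells; omitted")
      return(NULL)
    }
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = type,
                         names = FALSE)
    tibble::tibble(segment = i, n_valid = length(v), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  })
  dplyr::bind_rows(rows)
}
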