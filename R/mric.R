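# Motor-related IC detection, the zero-training minimum-variance
# classifier, two-round bad-trial rejection, and the ICA-T / ICA-S filter
# builders.

#' Detection filter set
#'
#' The three spatial filters extracting the motor-related sources:
#' `w_l` is the separating-matrix row of the C3-dominant (left-hemisphere)
#' component, `w_r` of the C4-dominant, and `w_f` of the Cz-dominant.
#' Under contralateral ERD, left-hand imagery suppresses the C4 source
#' (`u_r`), right-hand the C3 source (`u_l`), foot the Cz source (`u_f`).
#'
#' @param w_l,w_f,w_r Numeric spatial-filter rows of equal length.
#' @param channel_labels Channel names the filters apply to.
#' @param origin Trial index (or segment id) the filters were fitted on.
#' @return An object of class `detection_filters`.
#' @export
detection_filters <- function(w_l, w_f, w_r, channel_labels,
                              origin = NA_integer_) {
  w <- rbind(l = as.numeric(w_l), f = as.numeric(w_f), r = as.numeric(w_r))
  if (!all(is.finite(w))) stop("filters must be finite")
  if (ncol(w) != length(channel_labels))
    stop("filter length must match channel count")
  structure(list(w = w, channel_labels = as.character(channel_labels),
                 origin = origin),
            class = "detection_filters")
}

#' @export
print.detection_filters <- function(x, ...) {
  cat(sprintf("<detection_filters> 3 x %d (w_l, w_f, w_r), origin: %s\n",
              ncol(x$w), paste(x$origin, collapse = ",")))
  invisible(x)
}

#' Match motor-related ICs from a mixing matrix
#'
#' For each of C3, Cz and C4, finds the mixing-matrix columns whose
#' largest-magnitude entry lies at that channel; if several qualify, the
#' one with the largest magnitude at the channel wins. The trial "matches"
#' only when all three channels receive a (necessarily distinct) column;
#' otherwise it is a first-round bad trial.
#'
#' @param A Square mixing matrix (columns are spatial patterns).
#' @param labels Channel labels for the rows of `A`; must contain C3, Cz,
#'   C4.
#' @return An object of class `mric_assignment`: list with logical
#'   `matched` and (when matched) the column indices `ic_C3`, `ic_Cz`,
#'   `ic_C4`.
#' @export
match_mrics <- function(A, labels) {
  A <- as.matrix(A)
  targets <- c("C3", "Cz", "C4")
  rows <- match(targets, labels)
  if (anyNA(rows))
    stop("channel labels must contain C3, Cz and C4")
  peaks <- apply(abs(A), 2L, which.max)
  pick <- vapply(seq_along(targets), function(k) {
    cand <- which(peaks == rows[k])
    if (!length(cand)) return(NA_integer_)
    cand[which.max(abs(A[rows[k], cand]))]
  }, integer(1))
  matched <- !anyNA(pick)
  structure(list(matched = matched,
                 ic_C3 = pick[1], ic_Cz = pick[2], ic_C4 = pick[3]),
            class = "mric_assignment")
}

#' @export
print.mric_assignment <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<mric_assignment> matched: C3 -> IC%d, Cz -> IC%d, C4 -> IC%d\n",
                x$ic_C3, x$ic_Cz, x$ic_C4))
  else cat("<mric_assignment> not matched (bad trial)\n")
  invisible(x)
}

filters_from_model <- function(model, assignment, origin = NA_integer_) {
  detection_filters(w_l = model$W[assignment$ic_C3, ],
                    w_f = model$W[assignment$ic_Cz, ],
                    w_r = model$W[assignment$ic_C4, ],
                    channel_labels = model$channel_labels,
                    origin = origin)
}

#' First-round trial selection from single-trial ICA topographies
#'
#' Fits ICA to every trial individually (on the 8-30 Hz band data) and
#' labels a trial "good" when its mixing matrix contains three columns
#' peaking at C3, Cz and C4 ([match_mrics]). Each good trial yields a
#' [detection_filters] set from its assigned separating-matrix rows. An
#' ICA failure on a trial marks it bad (with a warning) rather than
#' aborting.
#'
#' @param trials A [trial_set] (band-filtered to 8-30 Hz).
#' @param cfg An [ica_config].
#' @return A list with `filters` (list, one [detection_filters] or `NULL`
#'   per trial) and `report` (a [selection_report] with round-1 labels;
#'   accuracies are filled by [st_bci_accuracies]).
#' @export
first_round_select <- function(trials, cfg = ica_config()) {
  stopifnot(inherits(trials, "trial_set"))
  n <- length(trials)
  if (n < 1) stop("need at least one trial")
  filters <- vector("list", n)
  good <- logical(n)
  for (i in seq_len(n)) {
    model <- tryCatch(fit_ica(trials$trials[[i]], cfg,
                              channel_labels = trials$channel_labels),
                      error = function(e) {
                        warning("ICA failed on trial ", trials$trial_index[i],
                                ": ", conditionMessage(e))
                        NULL
                      })
    if (is.null(model)) next
    asg <- match_mrics(model$A, trials$channel_labels)
    if (asg$matched) {
      good[i] <- TRUE
      filters[[i]] <- filters_from_model(model, asg,
                                         origin = trials$trial_index[i])
    }
  }
  report <- selection_report(trial_index = trials$trial_index,
                             label = trials$labels, round1_good = good)
  list(filters = filters, report = report)
}

#' Selection report
#'
#' Tabular record of the two-round trial selection: one row per trial with
#' its round-1 label, its st-BCI accuracy R_j (0 for round-1 bad trials,
#' matching how they are plotted), and the kept / top-m flags filled in by
#' [second_round_select] and [build_ica_t].
#'
#' @param trial_index 1-based trial positions.
#' @param label True class per trial.
#' @param round1_good Logical per trial.
#' @return An object of class `selection_report` wrapping a tibble.
#' @export
selection_report <- function(trial_index, label, round1_good) {
  data <- tibble::tibble(
    trial_index = as.integer(trial_index),
    label = as.integer(label),
    round1_good = round1_good,
    R_j = ifelse(round1_good, NA_real_, 0),
    kept = FALSE,
    in_top_m = FALSE)
  structure(list(data = data, threshold = NA_real_,
                 P = sum(round1_good), m = NA_integer_),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d trials, P = %d good after round 1",
              nrow(x$data), x$P))
  if (!is.na(x$threshold))
    cat(sprintf("; threshold %.3f, %d kept", x$threshold, sum(x$data$kept)))
  cat("\n")
  print(x$data, n = 5)
  invisible(x)
}

#' @rdname selection_report
#' @param x A `selection_report`.
#' @param ... Unused.
#' @export
tidy.selection_report <- function(x, ...) x$data

#' @rdname selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$data), P = x$P,
                 threshold = x$threshold, n_kept = sum(x$data$kept),
                 n_top_m = sum(x$data$in_top_m),
                 mean_R = mean(x$data$R_j[x$data$round1_good], na.rm = TRUE))
}

# Band-filter each trial to the subject band and cut the analysis window;
# done once so repeated filter evaluations stay cheap.
prepare_class_data <- function(trials, band, window) {
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$fs
  b <- design_bandpass(fs, band[1], band[2])
  i0 <- round(window[1] * fs)
  n <- round((window[2] - window[1]) * fs)
  if (n < 1) stop("zero-length analysis window")
  idx <- (i0 + 1L):(i0 + n)
  if (max(idx) > ncol(trials$trials[[1]]))
    stop("analysis window exceeds trial length")
  prepped <- lapply(trials$trials, function(x) {
    zero_phase_filter_mat(x, b)[, idx, drop = FALSE]
  })
  structure(list(trials = prepped, labels = trials$labels,
                 trial_index = trials$trial_index,
                 channel_labels = trials$channel_labels),
            class = "mi_class_data")
}

classify_prepared <- function(f, xw) {
  u <- f$w %*% xw
  v <- c(r = stats::var(u["r", ]), l = stats::var(u["l", ]),
         f = stats::var(u["f", ]))
  # classes listed in rule order: min var(u_r) -> left hand (1),
  # min var(u_l) -> right hand (2), min var(u_f) -> foot (3);
  # ties resolved by this order.
  as.integer(unname(which(v == min(v))[1]))
}

#' Zero-training classification of one trial
#'
#' Applies the three detection filters to the band-filtered trial
#' restricted to the analysis window, and assigns the class whose
#' contralateral motor source has minimum variance (the ERD signature):
#' class 1 (left hand) if `var(u_r)` is smallest, class 2 (right hand) if
#' `var(u_l)`, class 3 (foot) if `var(u_f)`. Ties go to the first class in
#' that order. No parameters are fitted.
#'
#' @param f A [detection_filters] set.
#' @param x Trial matrix (channels x samples) starting at the trial event.
#' @param band Length-2 Hz subject band (e.g. `c(10, 14)`).
#' @param window Length-2 seconds relative to trial start (e.g.
#'   `c(0.5, 5)`).
#' @param fs Sampling rate in Hz.
#' @return Integer class label in 1:3.
#' @export
classify_trial <- function(f, x, band, window, fs) {
  stopifnot(inherits(f, "detection_filters"))
  ts <- trial_set(list(as.matrix(x)), labels = 1L, fs = fs,
                  channel_labels = f$channel_labels)
  cd <- prepare_class_data(ts, band, window)
  classify_prepared(f, cd$trials[[1]])
}

#' Accuracy of a detection-filter set over a trial set
#'
#' Fraction of trials whose zero-training classification
#' ([classify_trial]) matches the true label.
#'
#' @param f A [detection_filters] set.
#' @param trials A [trial_set], or a prepared object from the internal
#'   band-filter/window step (used by the selection pipeline to avoid
#'   refiltering).
#' @param band,window As in [classify_trial] (ignored when `trials` is
#'   already prepared).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_filters <- function(f, trials, band, window) {
  stopifnot(inherits(f, "detection_filters"))
  cd <- if (inherits(trials, "mi_class_data")) trials
        else prepare_class_data(trials, band, window)
  if (!length(cd$trials)) stop("empty trial set")
  pred <- vapply(cd$trials, function(xw) classify_prepared(f, xw), 0)
  mean(pred == cd$labels)
}

#' Score every single-trial BCI
#'
#' Evaluates each good trial's detection filters over the whole training
#' set ([evaluate_filters]) and writes the accuracies R_j into the
#' selection report. Round-1 bad trials keep R_j = 0.
#'
#' @param fr Output of [first_round_select].
#' @param trials The training [trial_set].
#' @param band,window Subject band (Hz) and analysis window (s).
#' @return The updated list (`filters`, `report`).
#' @export
st_bci_accuracies <- function(fr, trials, band, window) {
  cd <- prepare_class_data(trials, band, window)
  rep <- fr$report
  for (i in seq_along(fr$filters)) {
    if (!is.null(fr$filters[[i]]))
      rep$data$R_j[i] <- evaluate_filters(fr$filters[[i]], cd)
  }
  fr$report <- rep
  fr
}

#' Second-round trial selection by st-BCI accuracy
#'
#' Bad trials of the second round are good trials whose st-BCI accuracy
#' R_j falls below a threshold. The default rule is the mean of the P
#' nonzero accuracies (round-1 bad trials, recorded as zero, are excluded
#' from the mean); trials with `R_j >= threshold` are kept.
#'
#' @param report A [selection_report] with R_j filled in.
#' @param rule `"mean"` (default), `"absolute"` or `"quantile"`.
#' @param value Threshold value for `"absolute"`, or probability for
#'   `"quantile"`.
#' @return The report with `threshold` and the `kept` column set.
#' @export
second_round_select <- function(report, rule = c("mean", "absolute",
                                                 "quantile"), value = NULL) {
  stopifnot(inherits(report, "selection_report"))
  rule <- match.arg(rule)
  d <- report$data
  good <- d$round1_good
  if (!any(good)) stop("no good trials survived the first round")
  if (anyNA(d$R_j[good])) stop("R_j not computed; run st_bci_accuracies first")
  r <- d$R_j[good]
  threshold <- switch(rule,
    mean = mean(r),
    absolute = { stopifnot(!is.null(value)); value },
    quantile = { stopifnot(!is.null(value)); stats::quantile(r, value,
                                                             names = FALSE) })
  d$kept <- good & d$R_j >= threshold
  report$data <- d
  report$threshold <- threshold
  report
}

# top-m kept trials by descending R_j, ties broken by ascending trial index
top_m_trials <- function(report, m) {
  d <- report$data[report$data$kept, ]
  d <- d[order(-d$R_j, d$trial_index), ]
  utils::head(d$trial_index, m)
}

#' Build the optimized ICA-T detection filters
#'
#' Concatenates the top-m kept trials (sorted by descending st-BCI
#' accuracy, ties by ascending trial index) along time, fits one ICA on
#' the concatenation, and matches the motor-related components. m = 10 is
#' the default for 8/9-channel montages. If fewer than m trials were kept,
#' all kept trials are used with a warning.
#'
#' @param trials The training [trial_set].
#' @param report A [selection_report] after [second_round_select].
#' @param m Number of top trials to concatenate.
#' @param cfg An [ica_config].
#' @return A list with `filters` (the final [detection_filters]), `model`
#'   (the fitted `mixing_model`) and `report` (with `in_top_m` set).
#' @export
build_ica_t <- function(trials, report, m = 10, cfg = ica_config()) {
  stopifnot(inherits(trials, "trial_set"), inherits(report, "selection_report"))
  if (is.na(report$threshold)) stop("run second_round_select first")
  top <- top_m_trials(report, m)
  if (length(top) < m)
    warning("only ", length(top), " kept trials available; using all of them")
  if (!length(top)) stop("no kept trials to build ICA-T from")
  pos <- match(top, trials$trial_index)
  X <- do.call(cbind, trials$trials[pos])
  model <- fit_ica(X, cfg, channel_labels = trials$channel_labels)
  asg <- match_mrics(model$A, trials$channel_labels)
  if (!asg$matched)
    stop("MRIC matching failed on the concatenated top-m trials; ",
         "try a different m or seed")
  report$data$in_top_m <- report$data$trial_index %in% top
  report$m <- as.integer(length(top))
  list(filters = filters_from_model(model, asg, origin = top),
       model = model, report = report)
}

#' Build sliding-window ICA-S detection filters
#'
#' Fits one ICA per sliding window of `win` consecutive trials (step
#' `step`), matching the motor-related components in each. Windows whose
#' matching fails yield `NULL` entries (with a warning). For 75 trials,
#' win 10 and step 1 this gives 66 windows.
#'
#' @param trials A [trial_set].
#' @param win Window length in trials.
#' @param step Step in trials.
#' @param cfg An [ica_config].
#' @return A list of [detection_filters] (or `NULL`), one per window;
#'   window j covers trials `j, ..., j + win - 1` (for `step = 1`).
#' @export
build_ica_s <- function(trials, win = 10, step = 1, cfg = ica_config()) {
  stopifnot(inherits(trials, "trial_set"))
  if (win <= 0 || step <= 0) stop("win and step must be positive")
  n <- length(trials)
  if (n < win) stop("need at least `win` trials")
  starts <- seq(1L, n - win + 1L, by = step)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + win - 1L)
    X <- do.call(cbind, trials$trials[idx])
    filt <- tryCatch({
      model <- fit_ica(X, cfg, channel_labels = trials$channel_labels)
      asg <- match_mrics(model$A, trials$channel_labels)
      if (!asg$matched) NULL
      else filters_from_model(model, asg, origin = trials$trial_index[idx])
    }, error = function(e) NULL)
    if (is.null(filt))
      warning("MRIC matching failed for window ", k)
    out[[k]] <- filt
  }
  out
}

#' Windows affected by artifact trials
#'
#' For a sliding-window scheme over trials, returns every window whose
#' trial range intersects the given artifact trial indices. With 75
#' trials, window 10 and step 1, artifact trials {43, 46} affect windows
#' 34 through 46.
#'
#' @param artifact_idx Integer trial indices.
#' @param n_trials Total number of trials.
#' @param win Window length in trials.
#' @param step Step in trials.
#' @return Sorted integer vector of affected window indices.
#' @export
affected_windows <- function(artifact_idx, n_trials, win = 10, step = 1) {
  artifact_idx <- as.integer(artifact_idx)
  if (any(artifact_idx < 1L | artifact_idx > n_trials))
    stop("artifact indices must lie in 1..n_trials")
  starts <- seq(1L, n_trials - win + 1L, by = step)
  hit <- vapply(seq_along(starts), function(k) {
    any(artifact_idx >= starts[k] & artifact_idx <= starts[k] + win - 1L)
  }, logical(1))
  which(hit)
}
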