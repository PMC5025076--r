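# End-to-end orchestration: preprocess -> train -> evaluate -> report
# files, for the four modes (ica-t, ica-s, csp, am).

#' Pipeline run configuration
#'
#' Validated bundle of every tunable the pipeline needs. Defaults follow
#' the standard few-channel motor-imagery setup: 8-30 Hz mu/beta band
#' before ICA, 50 Hz notch, nine-channel sensorimotor montage, 0.5-5 s
#' analysis window, a subject band of 10-14 Hz, top-10 trial
#' concatenation.
#'
#' @param band Length-2 Hz ICA band.
#' @param notch Notch frequency in Hz, or `NULL` to skip.
#' @param scheme `"eight"`, `"nine"`, a label vector, or `NULL` to keep
#'   all channels.
#' @param epoch_window Length-2 seconds relative to each event used for
#'   ICA fitting (the full trial by default).
#' @param window Length-2 seconds: the analysis window for classification
#'   variances.
#' @param subject_band Length-2 Hz classification band (10-14 or 12-16
#'   depending on the subject's reactive band; a configuration choice,
#'   not auto-detected).
#' @param m Top-m trial count for ICA-T.
#' @param win,step Sliding-window length and step (in trials) for ICA-S.
#' @param ica An [ica_config].
#' @param csp_frac,csp_repeats Training fraction and repeat count for the
#'   CSP self-test.
#' @param segmentation A [segmentation_params] (needed for `am` mode).
#' @param seed Integer seed controlling all pipeline randomness.
#' @return An object of class `run_config`.
#' @export
run_config <- function(band = c(8, 30), notch = 50, scheme = "nine",
                       epoch_window = c(0, 10), window = c(0.5, 5),
                       subject_band = c(10, 14), m = 10, win = 10, step = 1,
                       ica = ica_config(), csp_frac = 0.8, csp_repeats = 30,
                       segmentation = NULL, seed = 1) {
  stopifnot(length(band) == 2, band[1] < band[2],
            length(window) == 2, window[1] < window[2],
            length(subject_band) == 2, subject_band[1] < subject_band[2],
            m >= 1, win >= 1, step >= 1,
            csp_frac > 0, csp_frac <= 1, csp_repeats >= 1)
  if (!is.null(segmentation)) stopifnot(inherits(segmentation,
                                                 "segmentation_params"))
  structure(list(band = band, notch = notch, scheme = scheme,
                 epoch_window = epoch_window, window = window,
                 subject_band = subject_band, m = m, win = win, step = step,
                 ica = ica, csp_frac = csp_frac, csp_repeats = csp_repeats,
                 segmentation = segmentation, seed = as.integer(seed)),
            class = "run_config")
}

#' Preprocess a recording for ICA/CSP
#'
#' Notch, band-pass, channel selection and epoching in the standard
#' order; returns the epoched [trial_set] ready for single-trial ICA.
#'
#' @param rec An [eeg_recording].
#' @param cfg A [run_config].
#' @return A [trial_set].
#' @export
preprocess_recording <- function(rec, cfg = run_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "run_config"))
  if (!is.null(cfg$notch) && cfg$notch < rec$fs / 2)
    rec <- notch_filter(rec, cfg$notch)
  rec <- bandpass_filter(rec, cfg$band[1], cfg$band[2])
  if (!is.null(cfg$scheme)) {
    sch <- if (is.character(cfg$scheme)) channel_scheme(cfg$scheme)
           else cfg$scheme
    if (!all(sch$labels %in% rec$channel_labels) &&
        setequal(rec$channel_labels, sch$labels)) sch <- NULL
    if (!is.null(sch)) rec <- select_channels(rec, sch)
  }
  epoch_trials(rec, cfg$epoch_window)
}

#' Two-round trial selection in one call
#'
#' Convenience wrapper: first-round topography matching, st-BCI scoring,
#' second-round accuracy thresholding.
#'
#' @param trials A [trial_set].
#' @param cfg A [run_config].
#' @return A list with `filters` (per-trial detection filters or `NULL`)
#'   and `report` (a thresholded [selection_report]).
#' @export
two_round_selection <- function(trials, cfg = run_config()) {
  fr <- first_round_select(trials, cfg$ica)
  fr <- st_bci_accuracies(fr, trials, cfg$subject_band, cfg$window)
  fr$report <- second_round_select(fr$report)
  fr
}

#' Run the full pipeline and write report files
#'
#' Executes preprocess -> train -> evaluate for the chosen mode and
#' writes models/reports under `out_dir`:
#' \describe{
#'   \item{`ica-t`}{two-round selection + top-m concatenation; writes
#'     `filters.json`, `model.json`, `report.csv`, `summary.json`.}
#'   \item{`ica-s`}{sliding-window filters; writes `ica_s.csv` (window,
#'     accuracy) and `summary.json`.}
#'   \item{`csp`}{randomized CSP self-test; writes `csp.csv` and
#'     `summary.json`.}
#'   \item{`am`}{segment-level accuracy matrix (self-test, or against
#'     `test`); writes `accuracy_matrix.csv` and `summary.json`.}
#' }
#'
#' @param rec An [eeg_recording] (or a run directory path readable by
#'   [read_run]).
#' @param mode One of `"ica-t"`, `"ica-s"`, `"csp"`, `"am"`.
#' @param cfg A [run_config].
#' @param out_dir Output directory (created if needed).
#' @param test Optional test [eeg_recording] (or path) for `am` transfer;
#'   defaults to self-testing.
#' @return Invisibly, a list of the objects computed.
#' @export
run_pipeline <- function(rec, mode = c("ica-t", "ica-s", "csp", "am"),
                         cfg = run_config(), out_dir = ".", test = NULL) {
  mode <- match.arg(mode)
  if (is.character(rec)) rec <- read_run(rec)
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  trials <- preprocess_recording(rec, cfg)
  message(sprintf("[preprocess] %d trials, %d channels, band %g-%g Hz, seed %d",
                  length(trials), length(trials$channel_labels),
                  cfg$band[1], cfg$band[2], cfg$seed))

  if (mode == "ica-t") {
    sel <- two_round_selection(trials, cfg)
    res <- build_ica_t(trials, sel$report, m = cfg$m, cfg$ica)
    acc <- evaluate_filters(res$filters, trials, cfg$subject_band,
                            cfg$window)
    message(sprintf("[ica-t] P = %d, threshold %.3f, kept %d, top-m %d, self-test %.3f",
                    res$report$P, res$report$threshold,
                    sum(res$report$data$kept), res$report$m, acc))
    write_filters(res$filters, file.path(out_dir, "filters.json"))
    write_model(res$model, file.path(out_dir, "model.json"))
    write_report(res$report, file.path(out_dir, "report.csv"),
                 file.path(out_dir, "summary.json"))
    return(invisible(list(report = res$report, filters = res$filters,
                          accuracy = acc)))
  }

  if (mode == "ica-s") {
    flt <- build_ica_s(trials, win = cfg$win, step = cfg$step, cfg$ica)
    cd <- prepare_class_data(trials, cfg$subject_band, cfg$window)
    acc <- vapply(flt, function(f)
      if (is.null(f)) NA_real_ else evaluate_filters(f, cd), 0)
    message(sprintf("[ica-s] %d windows, mean accuracy %.3f",
                    length(flt), mean(acc, na.rm = TRUE)))
    utils::write.csv(data.frame(window = seq_along(acc), accuracy = acc),
                     file.path(out_dir, "ica_s.csv"), row.names = FALSE)
    jsonlite::write_json(list(n_windows = length(acc),
                              mean_accuracy = mean(acc, na.rm = TRUE)),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(filters = flt, accuracy = acc)))
  }

  if (mode == "csp") {
    cd_trials <- epoch_window_trials(trials, cfg$window)
    st <- csp_self_test(cd_trials, frac = cfg$csp_frac,
                        repeats = cfg$csp_repeats, seed = cfg$seed)
    message(sprintf("[csp] %d repeats, accuracy %.3f +/- %.3f",
                    cfg$csp_repeats, attr(st, "mean"), attr(st, "sd")))
    utils::write.csv(st, file.path(out_dir, "csp.csv"), row.names = FALSE)
    jsonlite::write_json(list(repeats = cfg$csp_repeats,
                              mean_accuracy = attr(st, "mean"),
                              sd_accuracy = attr(st, "sd")),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(self_test = st)))
  }

  # mode == "am"
  if (is.null(cfg$segmentation))
    stop("am mode needs cfg$segmentation (a segmentation_params)")
  test_trials <- if (is.null(test)) trials else {
    if (is.character(test)) test <- read_run(test)
    preprocess_recording(test, cfg)
  }
  am <- build_accuracy_matrix(trials, test_trials, cfg$segmentation,
                              cfg$subject_band, cfg$window, cfg$ica)
  ok <- am$values >= 0
  message(sprintf("[am] %d x %d matrix, %d valid cells, mean %.3f",
                  nrow(am$values), ncol(am$values), sum(ok),
                  mean(am$values[ok])))
  write_accuracy_matrix(am, file.path(out_dir, "accuracy_matrix.csv"))
  jsonlite::write_json(list(M = nrow(am$values), L = ncol(am$values),
                            n_valid = sum(ok),
                            mean_accuracy = mean(am$values[ok])),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(am = am))
}

# Re-cut already-epoched trials to a sub-window (seconds relative to the
# epoch start); used to hand CSP its 0.5-5 s training segment.
epoch_window_trials <- function(trials, window) {
  fs <- trials$fs
  i0 <- round(window[1] * fs)
  n <- round((window[2] - window[1]) * fs)
  idx <- (i0 + 1L):(i0 + n)
  cut <- lapply(trials$trials, function(x) x[, idx, drop = FALSE])
  trial_set(cut, trials$labels, fs, trials$channel_labels,
            trial_index = trials$trial_index, window = window)
}
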