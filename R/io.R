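# Native run format: a whitespace-separated numeric matrix (channels x
# samples), an events sidecar CSV (onset_sample, label) and a JSON header
# (fs, channel_labels). Plus JSON serialization of models, filters and
# reports.

#' Write / read a recording in the native run format
#'
#' A run directory holds `header.json` (`fs`, `channel_labels`),
#' `samples.txt` (channels x samples, one channel per row) and
#' `events.csv` (`onset_sample`, `label`).
#'
#' @param rec An [eeg_recording].
#' @param path Directory to write to / read from.
#' @return `write_run` returns `path` invisibly; `read_run` returns the
#'   validated [eeg_recording].
#' @export
write_run <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels),
                       file.path(path, "header.json"), auto_unbox = TRUE,
                       digits = NA)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  txt <- apply(rec$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(txt, file.path(path, "samples.txt"))
  ev <- rec$events
  names(ev) <- c("onset_sample", "label")
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  hdr_file <- file.path(path, "header.json")
  mat_file <- file.path(path, "samples.txt")
  ev_file <- file.path(path, "events.csv")
  for (f in c(hdr_file, mat_file, ev_file))
    if (!file.exists(f)) stop("missing run file: ", f)
  hdr <- jsonlite::read_json(hdr_file, simplifyVector = TRUE)
  if (is.null(hdr$fs) || is.null(hdr$channel_labels))
    stop("malformed header ", hdr_file, ": needs fs and channel_labels")
  mat <- as.matrix(utils::read.table(mat_file, header = FALSE))
  dimnames(mat) <- NULL
  if (nrow(mat) != length(hdr$channel_labels))
    stop("samples.txt has ", nrow(mat), " rows but header lists ",
         length(hdr$channel_labels), " channels")
  ev <- utils::read.csv(ev_file)
  if (!all(c("onset_sample", "label") %in% names(ev)))
    stop("malformed events file ", ev_file,
         ": needs onset_sample and label columns")
  eeg_recording(mat, hdr$fs, hdr$channel_labels,
                data.frame(onset = ev$onset_sample, label = ev$label))
}

#' Serialize detection filters or a mixing model to JSON
#'
#' @param x A [detection_filters] or `mixing_model`.
#' @param path File to write.
#' @return `path` invisibly; readers return the reconstructed object.
#' @export
write_filters <- function(x, path) {
  stopifnot(inherits(x, "detection_filters"))
  jsonlite::write_json(
    list(type = "detection_filters", channel_labels = x$channel_labels,
         origin = x$origin,
         w_l = x$w["l", ], w_f = x$w["f", ], w_r = x$w["r", ]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_filters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "detection_filters"))
    stop(path, " does not contain detection filters")
  detection_filters(j$w_l, j$w_f, j$w_r, j$channel_labels,
                    origin = j$origin)
}

#' @rdname write_filters
#' @export
write_model <- function(x, path) {
  stopifnot(inherits(x, "mixing_model"))
  jsonlite::write_json(
    list(type = "mixing_model", channel_labels = x$channel_labels,
         A = as.vector(t(x$A)), W = as.vector(t(x$W)),  # row-major
         n = nrow(x$A), converged = x$converged, n_iter = x$n_iter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "mixing_model"))
    stop(path, " does not contain a mixing model")
  n <- j$n
  structure(list(A = matrix(j$A, n, n, byrow = TRUE),
                 W = matrix(j$W, n, n, byrow = TRUE),
                 U = NULL, channel_labels = j$channel_labels,
                 converged = j$converged, n_iter = j$n_iter),
            class = "mixing_model")
}

#' @rdname write_filters
#' @export
write_csp_model <- function(x, path) {
  stopifnot(inherits(x, "csp_ovr"))
  jsonlite::write_json(
    list(type = "csp_ovr", channel_labels = x$channel_labels,
         splits = lapply(x$splits, function(s) list(
           class = s$pair$class_pair[1],
           filters = as.vector(t(s$pair$filters)),   # row-major, 2 x N
           eigvals = as.numeric(s$pair$eigvals),
           disc = s$disc))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_csp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "csp_ovr")) stop(path, " is not a CSP model")
  chl <- unlist(j$channel_labels)
  splits <- lapply(j$splits, function(s) {
    pair <- structure(
      list(filters = matrix(unlist(s$filters), 2, length(chl),
                            byrow = TRUE),
           eigvals = unlist(s$eigvals), W_full = NULL,
           class_pair = c(as.integer(s$class), 0L)),
      class = "csp_pair")
    disc <- list(a = unlist(s$disc$a), m = unlist(s$disc$m),
                 d = as.numeric(s$disc$d),
                 logit0 = as.numeric(s$disc$logit0))
    list(pair = pair, disc = disc)
  })
  structure(list(splits = splits, channel_labels = chl),
            class = "csp_ovr")
}

#' Export a selection report
#'
#' Writes the per-trial table as CSV (`trial_index`, `label`,
#' `round1_label`, `R_j`, `kept`, `in_top_m`) and a JSON summary
#' (P, threshold, kept and top-m trial indices).
#'
#' @param report A [selection_report].
#' @param csv_path,json_path Output files (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "selection_report"))
  d <- report$data
  if (!is.null(csv_path)) {
    out <- data.frame(trial_index = d$trial_index, label = d$label,
                      round1_label = ifelse(d$round1_good, "good", "bad"),
                      R_j = d$R_j, kept = d$kept, in_top_m = d$in_top_m)
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_trials = nrow(d), P = report$P, threshold = report$threshold,
           kept_trials = d$trial_index[d$kept],
           top_m = d$trial_index[d$in_top_m],
           mean_R = mean(d$R_j[d$round1_good])),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Export an accuracy matrix as CSV
#'
#' Cells are written with 1-based segment rows and trial columns matching
#' the (i, j) convention; sentinel -1 marks segments where no BCI could
#' be built.
#'
#' @param am An `accuracy_matrix`.
#' @param path CSV file to write.
#' @return `path` invisibly.
#' @export
write_accuracy_matrix <- function(am, path) {
  stopifnot(inherits(am, "accuracy_matrix"))
  v <- am$values
  df <- as.data.frame(v)
  names(df) <- paste0("trial_", seq_len(ncol(v)))
  df <- cbind(segment = seq_len(nrow(v)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
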