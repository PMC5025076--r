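#' Construct a multichannel EEG recording
#'
#' The basic container for continuous labeled EEG: a channels-by-samples
#' matrix in microvolts plus sampling rate, 10-20 channel labels, and
#' per-trial event markers.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of 10-20 system channel names, one
#'   per row of `samples`.
#' @param events Data frame with columns `onset` (1-based sample index of
#'   trial start, strictly increasing) and `label` (class, one of 1, 2, 3:
#'   left hand, right hand, foot). May be `NULL` or empty for an unlabeled
#'   recording.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 500), 2), fs = 250,
#'                      channel_labels = c("C3", "C4"),
#'                      events = data.frame(onset = 1L, label = 1L))
#' rec
eeg_recording <- function(samples, fs, channel_labels, events = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("length(channel_labels) must equal nrow(samples)")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be distinct")
  if (is.null(events)) {
    events <- data.frame(onset = integer(0), label = integer(0))
  }
  events <- as.data.frame(events)
  if (!all(c("onset", "label") %in% names(events)))
    stop("`events` needs columns `onset` and `label`")
  events$onset <- as.integer(events$onset)
  events$label <- as.integer(events$label)
  if (nrow(events)) {
    if (any(diff(events$onset) <= 0))
      stop("event onsets must be strictly increasing")
    if (events$onset[1] < 1L || events$onset[nrow(events)] > ncol(samples))
      stop("event onsets must lie within the sample range")
    if (!all(events$label %in% 1:3))
      stop("event labels must be in {1, 2, 3}")
  }
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

#' Electrode montage schemes
#'
#' The two reduced montages used for few-channel motor-imagery work: an
#' eight-channel scheme spanning frontal, central and occipital sites, and a
#' nine-channel scheme concentrated over sensorimotor cortex.
#'
#' @param name `"eight"`, `"nine"`, or a character vector of channel labels
#'   for a custom scheme.
#' @return An object of class `channel_scheme` (a named list with `name` and
#'   ordered `labels`).
#' @export
#' @examples
#' channel_scheme("nine")
channel_scheme <- function(name) {
  if (length(name) == 1L && name %in% c("eight", "nine")) {
    labels <- switch(name,
      eight = c("FP1", "FP2", "C3", "Cz", "C4", "O1", "Oz", "O2"),
      nine  = c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CPz", "CP4"))
    nm <- name
  } else {
    labels <- as.character(name)
    nm <- "custom"
  }
  if (anyDuplicated(labels)) stop("scheme labels must be distinct")
  structure(list(name = nm, labels = labels), class = "channel_scheme")
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("<channel_scheme> %s: %s\n", x$name,
              paste(x$labels, collapse = " ")))
  invisible(x)
}

# Approximate 2-D scalp positions (unit head circle, nose up) for the 10-20
# labels this package works with; used for Gaussian source topographies and
# topography plotting, not for any head-model computation.
montage_coords <- function(labels) {
  tab <- matrix(c(
    -0.31,  0.95,   # FP1
     0.31,  0.95,   # FP2
    -0.55,  0.70,   # F3
     0.00,  0.72,   # Fz
     0.55,  0.70,   # F4
    -0.95,  0.31,   # F7
     0.95,  0.31,   # F8
    -0.50,  0.35,   # FC3
     0.00,  0.36,   # FCz
     0.50,  0.35,   # FC4
    -0.50,  0.00,   # C3
     0.00,  0.00,   # Cz
     0.50,  0.00,   # C4
    -0.50, -0.35,   # CP3
     0.00, -0.36,   # CPz
     0.50, -0.35,   # CP4
    -0.55, -0.70,   # P3
     0.00, -0.72,   # Pz
     0.55, -0.70,   # P4
    -0.31, -0.95,   # O1
     0.00, -1.00,   # Oz
     0.31, -0.95),  # O2
    ncol = 2, byrow = TRUE)
  rownames(tab) <- c("FP1", "FP2", "F3", "Fz", "F4", "F7", "F8",
                     "FC3", "FCz", "FC4", "C3", "Cz", "C4",
                     "CP3", "CPz", "CP4", "P3", "Pz", "P4",
                     "O1", "Oz", "O2")
  missing <- setdiff(labels, rownames(tab))
  if (length(missing))
    stop("no montage coordinates for channel(s): ",
         paste(missing, collapse = ", "))
  tab[labels, , drop = FALSE]
}

#' Select and reorder channels of a recording
#'
#' Pure row permutation/subset: the returned rows are taken verbatim from the
#' source recording, in the scheme's order. All other metadata (sampling
#' rate, events) is preserved.
#'
#' @param rec An [eeg_recording].
#' @param scheme A [channel_scheme] or character vector of labels.
#' @return An [eeg_recording] restricted to the scheme's channels.
#' @export
select_channels <- function(rec, scheme) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(scheme)) scheme <- channel_scheme(scheme)
  idx <- match(scheme$labels, rec$channel_labels)
  if (anyNA(idx))
    stop("channel(s) not found in recording: ",
         paste(scheme$labels[is.na(idx)], collapse = ", "))
  eeg_recording(rec$samples[idx, , drop = FALSE], rec$fs,
                rec$channel_labels[idx], rec$events)
}
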