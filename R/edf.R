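# Minimal European Data Format (EDF/EDF+C) reader and writer.
#
# Covers what EEG run exchange needs: 16-bit data records with per-signal
# physical/digital scaling, and an "EDF Annotations" signal (EDF+ TALs)
# carrying the trial markers. Not a general EDF implementation
# (no discontinuous files, no sub-second record durations).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF+
#'
#' One data record per second (the sampling rate must be a whole number).
#' Each channel is scaled to the 16-bit digital range over its own
#' physical range; events are stored as EDF+ annotations whose text is the
#' class label.
#'
#' @param rec An [eeg_recording] with integer `fs`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer needs an integer sampling rate")
  N <- nrow(rec$samples)
  n_rec <- ceiling(ncol(rec$samples) / fs)
  total <- n_rec * fs
  X <- cbind(rec$samples,
             matrix(0, N, total - ncol(rec$samples)))  # pad last record

  # physical/digital scaling per channel
  pmin <- apply(X, 1, min); pmax <- apply(X, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((X - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"

  # annotation TALs per record; every TAL is NUL-terminated
  tals <- lapply(seq_len(n_rec), function(r) sprintf("+%d\x14\x14", r - 1L))
  if (nrow(rec$events)) {
    onset_s <- (rec$events$onset - 1) / fs
    rec_of <- pmin(floor(onset_s), n_rec - 1L) + 1L
    for (k in seq_len(nrow(rec$events)))
      tals[[rec_of[k]]] <- c(tals[[rec_of[k]]],
        sprintf("+%.6f\x14%s\x14", onset_s[k], rec$events$label[k]))
  }
  tal_bytes <- lapply(tals, function(s)
    unlist(lapply(s, function(t) c(charToRaw(t), as.raw(0)))))
  ann_len <- max(vapply(tal_bytes, length, 0L))
  ann_len <- ann_len + (ann_len %% 2L)        # even byte count
  ann_ns <- ann_len %/% 2L                    # 2-byte "samples"

  ns <- N + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad_field(x, width)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("EDF+C", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labs <- c(rec$channel_labels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= N) "uV" else "", 8)  # dimension
  for (i in seq_len(ns)) wr(if (i <= N) sprintf("%.6g", pmin[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= N) sprintf("%.6g", pmax[i]) else "1", 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(if (i <= N) fs else ann_ns, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(N))
      writeBin(dig[i, idx], con, size = 2, endian = "little")
    tb <- tal_bytes[[r]]
    writeBin(c(tb, raw(ann_len - length(tb))), con)
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  list(version = version, reserved = reserved, n_rec = n_rec, dur = dur,
       ns = ns,
       label = fld(16), transducer = fld(80), dim = fld(8),
       pmin = as.numeric(fld(8)), pmax = as.numeric(fld(8)),
       dmin = as.numeric(fld(8)), dmax = as.numeric(fld(8)),
       prefilter = fld(80), nsamp = as.integer(fld(8)), sreserved = fld(32))
}

parse_tals <- function(bytes) {
  # TALs are NUL-separated; fields within a TAL by \x14, duration by \x15
  out <- list()
  zero <- which(bytes == as.raw(0))
  start <- 1L
  for (z in zero) {
    if (z > start) {
      tal <- rawToChar(bytes[start:(z - 1L)])
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        onset <- suppressWarnings(
          as.numeric(strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1]))
        if (!is.na(onset))
          for (lab in parts[-1])
            if (nzchar(lab))
              out[[length(out) + 1L]] <- list(onset = onset, text = lab)
      }
    }
    start <- z + 1L
  }
  out
}

#' Read an EDF/EDF+ file as a recording
#'
#' Reads the 16-bit data records, rescales each signal to physical units,
#' and maps EDF+ annotations to trial events via `label_map`. All data
#' signals must share one sampling rate.
#'
#' @param path EDF file.
#' @param label_map Named integer vector mapping annotation texts to class
#'   labels (default maps `"1"/"2"/"3"`); annotations with unmapped texts
#'   are ignored.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, label_map = c(`1` = 1L, `2` = 2L, `3` = 3L)) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  is_ann <- h$label == "EDF Annotations"
  sig <- which(!is_ann)
  if (!length(sig)) stop(path, ": no data signals")
  fs <- h$nsamp[sig] / h$dur
  if (length(unique(fs)) != 1L)
    stop(path, ": signals with mixed sampling rates are not supported")
  fs <- fs[1]
  X <- matrix(0, length(sig), h$n_rec * h$nsamp[sig[1]])
  anns <- list()
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$ns)) {
      if (is_ann[i]) {
        anns <- c(anns, parse_tals(readBin(con, "raw", 2L * h$nsamp[i])))
      } else {
        d <- readBin(con, "integer", h$nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
        k <- match(i, sig)
        idx <- ((r - 1L) * h$nsamp[i] + 1L):(r * h$nsamp[i])
        X[k, idx] <- (d - h$dmin[i]) / (h$dmax[i] - h$dmin[i]) *
          (h$pmax[i] - h$pmin[i]) + h$pmin[i]
      }
    }
  }
  ev <- data.frame(onset = integer(0), label = integer(0))
  if (length(anns)) {
    lab <- unname(label_map[vapply(anns, `[[`, "", "text")])
    keep <- !is.na(lab)
    if (any(keep)) {
      onset <- round(vapply(anns, `[[`, 0, "onset")[keep] * fs) + 1L
      ev <- data.frame(onset = onset, label = lab[keep])
      ev <- ev[order(ev$onset), ]
    }
  }
  eeg_recording(X, fs, h$label[sig], ev)
}
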