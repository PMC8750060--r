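# Minimal European Data Format (EDF) support: 16-bit samples, one-second data
# records, enough to exchange continuous multichannel EEG with standard
# viewers. EDF has no native class-label field, so the subject id is stored in
# the patient field and "class=<0|1>" in the recording field.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

write_ascii <- function(con, x, width) {
  writeChar(pad_field(x, width), con, nchars = width, eos = NULL)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range.
#' The recording is truncated to a whole number of one-second data records.
#'
#' @param rec An [eeg_recording()]; `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  write_ascii(con, "0", 8L)
  write_ascii(con, rec$subject_id, 80L)
  write_ascii(con, sprintf("class=%d", rec$class_label), 80L)
  write_ascii(con, "01.01.00", 8L)
  write_ascii(con, "00.00.00", 8L)
  write_ascii(con, 256L + ns * 256L, 8L)
  write_ascii(con, "", 44L)
  write_ascii(con, n_rec, 8L)
  write_ascii(con, 1L, 8L)
  write_ascii(con, ns, 4L)
  for (lab in rec$channel_labels) write_ascii(con, lab, 16L)
  for (i in seq_len(ns)) write_ascii(con, "", 80L)
  for (i in seq_len(ns)) write_ascii(con, "uV", 8L)
  for (i in seq_len(ns)) write_ascii(con, sprintf("%.8g", pmin_[i]), 8L)
  for (i in seq_len(ns)) write_ascii(con, sprintf("%.8g", pmax_[i]), 8L)
  for (i in seq_len(ns)) write_ascii(con, dmin, 8L)
  for (i in seq_len(ns)) write_ascii(con, dmax, 8L)
  for (i in seq_len(ns)) write_ascii(con, "", 80L)
  for (i in seq_len(ns)) write_ascii(con, fs, 8L)
  for (i in seq_len(ns)) write_ascii(con, "", 32L)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[i, cols] - pmin_[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(con, width) {
  trimws(readChar(con, nchars = width, useBytes = TRUE))
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with identical sampling rate across signals. The
#' class label is recovered from a `class=<n>` token in the recording field
#' when present, else `NA`.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8L)                       # version
  subject_id <- read_ascii(con, 80L)
  rec_field <- read_ascii(con, 80L)
  read_ascii(con, 8L); read_ascii(con, 8L)  # date, time
  read_ascii(con, 8L); read_ascii(con, 44L) # header bytes, reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))

  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16L), character(1))
  for (i in seq_len(ns)) read_ascii(con, 80L)   # transducer
  for (i in seq_len(ns)) read_ascii(con, 8L)    # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), numeric(1))
  for (i in seq_len(ns)) read_ascii(con, 80L)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8L)), integer(1))
  for (i in seq_len(ns)) read_ascii(con, 32L)   # reserved

  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      samples[i, cols] <- pmin_[i] + (dig - dmin[i]) * gain[i]
    }
  }
  class_label <- if (grepl("class=[01]", rec_field)) {
    as.integer(sub(".*class=([01]).*", "\\1", rec_field))
  } else {
    NA_integer_
  }
  eeg_recording(samples, fs = fs, channel_labels = labels,
                subject_id = subject_id,
                class_label = if (is.na(class_label)) 0L else class_label)
}
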