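#' EEG recording container
#'
#' One subject's multichannel EEG: a channels x time matrix of voltages
#' (microvolts) with sampling rate, channel labels, subject id and class
#' label (0 healthy, 1 MDD).
#'
#' @param samples Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id Subject identifier.
#' @param class_label 0 or 1.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels, subject_id, class_label) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("`samples` must have at least one channel and one sample", call. = FALSE)
  }
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must equal the channel count", call. = FALSE)
  }
  if (!class_label %in% c(0L, 1L)) {
    stop("`class_label` must be 0 (healthy) or 1 (MDD)", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      fs = fs,
      channel_labels = as.character(channel_labels),
      subject_id = as.character(subject_id),
      class_label = as.integer(class_label)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, class %d, %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$class_label, nrow(x$samples), ncol(x$samples), x$fs,
    ncol(x$samples) / x$fs
  ))
  invisible(x)
}

#' Cut a recording into fixed-length windows
#'
#' Non-overlapping consecutive windows starting at sample 0; the trailing
#' remainder shorter than one window is discarded, so the window count is
#' `floor(n_samples / window)`.
#'
#' @param rec An [eeg_recording()].
#' @param window Window length in samples (default 1024, i.e. 4 s at 256 Hz).
#' @return List of channels x window matrices, each with attribute
#'   `start_index` (0-based sample offset).
#' @export
segment_recording <- function(rec, window = 1024L) {
  stopifnot(inherits(rec, "eeg_recording"))
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1 sample", call. = FALSE)
  n <- ncol(rec$samples)
  k <- n %/% window
  if (k == 0L) return(list())
  lapply(seq_len(k) - 1L, function(i) {
    w <- rec$samples[, (i * window + 1L):((i + 1L) * window), drop = FALSE]
    attr(w, "start_index") <- i * window
    w
  })
}

#' Reshape a window into the 3-D tensor the classifier consumes
#'
#' Per channel, the `n = a * b` time samples fill an `a x b` matrix row-major:
#' element (r, c) of the plane (0-based) holds time sample `b * r + c`, so
#' time order is preserved along rows. The map is exactly invertible via
#' [from_tensor()].
#'
#' @param window Channels x n numeric matrix (one segment).
#' @param a,b Plane dimensions; `a * b` must equal `n`.
#' @param class_label,subject_id,start_index Segment metadata.
#' @return An object of class `tensor_segment` with a `tensor` array of
#'   dimension channels x a x b.
#' @export
to_tensor <- function(window, a = 32L, b = 32L, class_label = NA_integer_,
                      subject_id = NA_character_, start_index = 0L) {
  window <- as.matrix(window)
  m <- nrow(window)
  n <- ncol(window)
  if (n != a * b) {
    stop(sprintf("window length %d is not a * b = %d", n, a * b), call. = FALSE)
  }
  tensor <- array(0, dim = c(m, a, b))
  for (ch in seq_len(m)) {
    # byrow fills rows left-to-right: time order along rows
    tensor[ch, , ] <- matrix(window[ch, ], nrow = a, ncol = b, byrow = TRUE)
  }
  structure(
    list(
      tensor = tensor,
      class_label = if (is.na(class_label)) NA_integer_ else as.integer(class_label),
      subject_id = as.character(subject_id),
      start_index = as.integer(start_index)
    ),
    class = "tensor_segment"
  )
}

#' Invert [to_tensor()]
#'
#' @param ts A `tensor_segment`.
#' @return The original channels x n window matrix.
#' @export
from_tensor <- function(ts) {
  stopifnot(inherits(ts, "tensor_segment"))
  d <- dim(ts$tensor)
  out <- matrix(0, nrow = d[1], ncol = d[2] * d[3])
  for (ch in seq_len(d[1])) {
    out[ch, ] <- as.vector(t(ts$tensor[ch, , ]))
  }
  out
}

#' Segment a whole cohort into tensors
#'
#' Applies [segment_recording()] then [to_tensor()] to every recording,
#' carrying subject id and class label onto each segment.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param window Window length in samples.
#' @param a,b Tensor plane dimensions (`a * b == window`).
#' @return List of `tensor_segment` objects.
#' @export
tensor_segments <- function(recordings, window = 1024L, a = 32L, b = 32L) {
  segs <- lapply(recordings, function(rec) {
    lapply(segment_recording(rec, window), function(w) {
      to_tensor(w, a = a, b = b, class_label = rec$class_label,
                subject_id = rec$subject_id, start_index = attr(w, "start_index"))
    })
  })
  unlist(segs, recursive = FALSE)
}

#' Subject-level train/test split
#'
#' Whole subjects are assigned to the test set, per class, until
#' `ceiling(test_fraction * n_subjects)` test subjects per class are reached;
#' no subject contributes segments to both sides. Deterministic given `seed`.
#'
#' @param segments List of `tensor_segment` objects.
#' @param test_fraction Fraction of subjects per class held out, in (0, 1).
#' @param seed Integer seed for the subject shuffle.
#' @return An object of class `dataset_split` with elements `train` and
#'   `test` (lists of segments).
#' @export
split_by_subject <- function(segments, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  subj <- vapply(segments, function(s) s$subject_id, character(1))
  lab <- vapply(segments, function(s) s$class_label, integer(1))
  subj_label <- tapply(lab, subj, function(v) v[1])
  test_subjects <- character(0)
  for (cl in sort(unique(subj_label))) {
    pool <- sort(names(subj_label)[subj_label == cl])
    if (length(pool) < 2L) {
      stop("need at least 2 subjects per class to split", call. = FALSE)
    }
    n_test <- max(1L, ceiling(test_fraction * length(pool)))
    if (n_test >= length(pool)) n_test <- length(pool) - 1L
    picked <- with_seed(derive_seed(seed, as.integer(cl) + 1L),
                        sample(pool, n_test))
    test_subjects <- c(test_subjects, picked)
  }
  is_test <- subj %in% test_subjects
  structure(
    list(train = segments[!is_test], test = segments[is_test]),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  f <- function(part) {
    subj <- unique(vapply(part, function(s) s$subject_id, character(1)))
    sprintf("%d segments from %d subjects", length(part), length(subj))
  }
  cat("<dataset_split>\n  train:", f(x$train), "\n  test: ", f(x$test), "\n")
  invisible(x)
}

#' Write a cohort to a plain-text container
#'
#' One directory per cohort: `cohort.json` holds sampling rate, channel
#' labels and the subject table; `recordings/<subject>.csv` holds one
#' time x channels matrix per subject.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    fs = recordings[[1]]$fs,
    channel_labels = recordings[[1]]$channel_labels,
    subjects = data.frame(
      subject_id = vapply(recordings, function(r) r$subject_id, character(1)),
      class_label = vapply(recordings, function(r) r$class_label, integer(1)),
      n_samples = vapply(recordings, function(r) ncol(r$samples), integer(1))
    )
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  for (r in recordings) {
    dt <- data.table::as.data.table(t(r$samples))
    data.table::setnames(dt, r$channel_labels)
    data.table::fwrite(dt, file.path(dir, "recordings", paste0(r$subject_id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List of [eeg_recording()] objects.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  lapply(seq_len(nrow(meta$subjects)), function(i) {
    sid <- meta$subjects$subject_id[i]
    dt <- data.table::fread(file.path(dir, "recordings", paste0(sid, ".csv")))
    eeg_recording(
      samples = t(as.matrix(dt)),
      fs = meta$fs,
      channel_labels = meta$channel_labels,
      subject_id = sid,
      class_label = meta$subjects$class_label[i]
    )
  })
}

#' Write a CSV manifest of segments
#'
#' @param segments List of `tensor_segment` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_manifest <- function(segments, path) {
  dt <- data.table::data.table(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    class_label = vapply(segments, function(s) s$class_label, integer(1)),
    start_index = vapply(segments, function(s) s$start_index, integer(1))
  )
  data.table::fwrite(dt, path)
  invisible(path)
}
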