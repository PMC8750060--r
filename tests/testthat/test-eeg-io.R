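test_that("segmentation yields floor(n/window) non-overlapping windows", {
  rec <- eeg_recording(matrix(seq_len(2 * 4096), nrow = 2), fs = 256,
                       channel_labels = c("a", "b"), subject_id = "S1",
                       class_label = 0L)
  w <- segment_recording(rec, 1024L)
  expect_length(w, 4L)
  expect_equal(attr(w[[4]], "start_index"), 3L * 1024L)
  # reconstruction: concatenated windows equal the first 4096 samples
  expect_equal(do.call(cbind, w), rec$samples[, 1:4096],
               ignore_attr = TRUE)

  rec5000 <- eeg_recording(matrix(rnorm(5000), nrow = 1), fs = 256,
                           channel_labels = "a", subject_id = "S1",
                           class_label = 0L)
  w5 <- segment_recording(rec5000, 1024L)
  expect_length(w5, 4L)
  expect_equal(attr(w5[[4]], "start_index"), 3072L)

  short <- eeg_recording(matrix(rnorm(10), nrow = 1), fs = 256,
                         channel_labels = "a", subject_id = "S1",
                         class_label = 0L)
  expect_length(segment_recording(short, 1024L), 0L)
})

test_that("a 1024-sample window at 256 Hz spans 4 seconds", {
  fs <- 256
  window <- 1024L
  expect_equal(window / fs, 4)
})

test_that("tensor reshape is row-major per channel and exactly invertible", {
  w <- matrix(0:1023, nrow = 1, byrow = TRUE)
  ts <- to_tensor(w, 32L, 32L)
  for (r in c(1L, 7L, 32L)) {
    for (cc in c(1L, 15L, 32L)) {
      expect_equal(ts$tensor[1, r, cc], 32 * (r - 1) + (cc - 1))
    }
  }
  set.seed(8)
  w2 <- matrix(rnorm(3 * 64), nrow = 3)
  ts2 <- to_tensor(w2, 8L, 8L)
  expect_equal(from_tensor(ts2), w2)
  expect_equal(to_tensor(matrix(0, 2, 64), 8L, 8L)$tensor,
               array(0, c(2, 8, 8)))
  expect_error(to_tensor(matrix(0, 2, 60), 8L, 8L), "a \\* b")
})

test_that("segment counts are conserved across a cohort", {
  cohort <- generate_cohort(mini_hg_profile(), mini_mg_profile(),
                            mini_spec(n_per_class = 3L, duration = 10))
  segs <- tensor_segments(cohort, window = 64L, a = 8L, b = 8L)
  expected <- sum(vapply(cohort, function(r) ncol(r$samples) %/% 64L,
                         integer(1)))
  expect_length(segs, expected)
})

test_that("subject-level split is disjoint, stratified and deterministic", {
  segs <- mini_segments(n_per_class = 10L, duration = 4)
  expect_error(split_by_subject(segs, 1.2), "between 0 and 1")
  sp <- split_by_subject(segs, 0.2, seed = 3L)
  train_subj <- unique(vapply(sp$train, function(s) s$subject_id, character(1)))
  test_subj <- unique(vapply(sp$test, function(s) s$subject_id, character(1)))
  expect_length(intersect(train_subj, test_subj), 0L)
  test_labels <- vapply(sp$test, function(s) s$class_label, integer(1))
  expect_length(unique(test_labels), 2L)
  # 10 subjects per class at 0.2 -> 2 test subjects per class
  expect_length(test_subj, 4L)
  sp2 <- split_by_subject(segs, 0.2, seed = 3L)
  expect_identical(
    sort(vapply(sp2$test, function(s) s$subject_id, character(1))),
    sort(vapply(sp$test, function(s) s$subject_id, character(1)))
  )
})

test_that("cohort text container round-trips", {
  cohort <- generate_cohort(mini_hg_profile(), mini_mg_profile(),
                            mini_spec(n_per_class = 2L, duration = 4))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, length(cohort))
  for (i in seq_along(cohort)) {
    expect_equal(back[[i]]$samples, cohort[[i]]$samples, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(back[[i]]$subject_id, cohort[[i]]$subject_id)
    expect_identical(back[[i]]$class_label, cohort[[i]]$class_label)
  }
  unlink(dir, recursive = TRUE)
})

test_that("EDF writer/reader round-trips within quantization error", {
  spec <- mini_spec(n_per_class = 1L, duration = 4)
  rec <- generate_recording(mini_mg_profile(), spec, "MDD S07", 1L, seed = 21L)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$class_label, 1L)
  # 16-bit quantization over the per-channel physical range
  qstep <- (apply(rec$samples, 1, max) - apply(rec$samples, 1, min)) / 65535
  expect_true(all(abs(back$samples - rec$samples) <= qstep + 1e-12))
  unlink(path)
})

test_that("segment manifest lists every segment with its metadata", {
  segs <- mini_segments(n_per_class = 2L, duration = 4)
  path <- tempfile(fileext = ".csv")
  write_segment_manifest(segs, path)
  man <- utils::read.csv(path)
  expect_equal(nrow(man), length(segs))
  expect_setequal(names(man), c("subject_id", "class_label", "start_index"))
  unlink(path)
})
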