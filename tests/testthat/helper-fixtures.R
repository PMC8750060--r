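# Small fixtures built in code: a miniature 4-channel cohort (32 Hz, 8 x 8
# tensors) keeps the unit tests fast while exercising the same code paths as
# the full-size 20 x 32 x 32 configuration.

mini_labels <- c("Fp1", "Fp2", "O1", "O2")

mini_spec <- function(n_per_class = 6L, duration = 8, seed = 11L) {
  cohort_spec(
    n_subjects_per_class = n_per_class, duration = duration, fs = 32,
    n_channels = 4L, channel_labels = mini_labels, seed = seed
  )
}

mini_hg_profile <- function() {
  spectral_class_profile(
    peaks = data.frame(frequency = 3, amplitude = 1, bandwidth = 0.5),
    noise_sd = 0.2
  )
}

mini_mg_profile <- function() {
  spectral_class_profile(
    peaks = data.frame(frequency = 7, amplitude = 1.2, bandwidth = 0.5),
    noise_sd = 0.2, power_scale = 1.5
  )
}

mini_segments <- function(n_per_class = 6L, duration = 8, seed = 11L) {
  cohort <- generate_cohort(mini_hg_profile(), mini_mg_profile(),
                            mini_spec(n_per_class, duration, seed))
  tensor_segments(cohort, window = 64L, a = 8L, b = 8L)
}

mini_model_config <- function(...) {
  model_config(conv = list(c(4L, 3L), c(6L, 3L)), fc_widths = c(16L, 8L, 1L),
               dropout_rate = 0.1, ...)
}

mini_input_shape <- c(4L, 8L, 8L)

# Reference affinity propagation through scikit-learn (independent oracle).
# Returns the exemplar count and the cluster label of every point.
sklearn_ap <- function(values, preference, damping, max_iter = 600L) {
  vf <- tempfile(fileext = ".txt")
  of <- tempfile(fileext = ".txt")
  on.exit(unlink(c(vf, of)))
  writeLines(format(values, digits = 17), vf)
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.cluster import AffinityPropagation\n",
    "x = np.loadtxt(%s).reshape(-1, 1)\n",
    "ap = AffinityPropagation(damping=%.17g, preference=%.17g, ",
    "max_iter=%d, random_state=0).fit(x)\n",
    "np.savetxt(%s, np.concatenate([[len(ap.cluster_centers_indices_)], ",
    "ap.labels_]))\n"),
    shQuote(vf), damping, preference, max_iter, shQuote(of))
  status <- system2("python", "-", input = code, stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L || !file.exists(of)) {
    stop("reference AP oracle failed to run")
  }
  out <- scan(of, quiet = TRUE)
  list(k = as.integer(out[1]), labels = as.integer(out[-1]) + 1L)
}

# Canonical form of a partition: cluster ids renumbered by first appearance,
# so two labelings describing the same grouping compare equal.
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
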