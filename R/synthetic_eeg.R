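#' Default 20-channel 10-20 montage
#'
#' The 19 electrodes of the five-region scalp map (frontal, left/right
#' temporal, central, occipital) plus the right ear-lobe reference "A2" as the
#' 20th channel. The montage is a documented choice and can be overridden in
#' [cohort_spec()].
#'
#' @return Character vector of 20 channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fp2", "F3", "F4",        # frontal lobe
    "F7", "T3", "T5",                # left temporal
    "C3", "C4", "Fz", "Cz", "Pz",    # central
    "F8", "T4", "T6",                # right temporal
    "P3", "P4", "O1", "O2",          # occipital lobe
    "A2"                             # right ear lobe, 20th channel
  )
}

#' Spectral class profile for synthetic EEG
#'
#' Describes one diagnostic class as a set of narrow-band oscillatory peaks on
#' top of a 1/f^a background. Each peak is given as (frequency in Hz,
#' amplitude in microvolts, bandwidth in Hz); the bandwidth bounds a uniform
#' per-channel frequency jitter so channels are not phase- or
#' frequency-locked.
#'
#' @param peaks Numeric matrix or data.frame with columns `frequency`,
#'   `amplitude`, `bandwidth` (one row per peak).
#' @param background_exponent Slope `a` of the 1/f^a background spectrum.
#' @param noise_sd Standard deviation (microvolts) of the background noise.
#' @param power_scale Multiplier on total signal power; amplitudes are scaled
#'   by `sqrt(power_scale)` so power scales linearly.
#' @return An object of class `spectral_class_profile`.
#' @export
spectral_class_profile <- function(peaks, background_exponent = 1.0,
                                   noise_sd = 0.3, power_scale = 1.0) {
  peaks <- as.data.frame(peaks)
  required <- c("frequency", "amplitude", "bandwidth")
  if (!all(required %in% names(peaks))) {
    stop("`peaks` needs columns frequency, amplitude, bandwidth", call. = FALSE)
  }
  if (nrow(peaks) < 1L) stop("at least one peak is required", call. = FALSE)
  if (any(!is.finite(as.matrix(peaks[required])))) {
    stop("peak parameters must be finite", call. = FALSE)
  }
  if (any(peaks$frequency <= 0)) {
    stop("peak frequencies must be strictly positive", call. = FALSE)
  }
  if (any(peaks$amplitude <= 0) || any(peaks$bandwidth <= 0)) {
    stop("peak amplitudes and bandwidths must be strictly positive", call. = FALSE)
  }
  stop_if_not_scalar_number(background_exponent, "background_exponent")
  stop_if_not_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  stop_if_not_scalar_number(power_scale, "power_scale", positive = TRUE)
  structure(
    list(
      peaks = peaks[required],
      background_exponent = background_exponent,
      noise_sd = noise_sd,
      power_scale = power_scale
    ),
    class = "spectral_class_profile"
  )
}

#' Default healthy-control spectral profile
#'
#' Oscillatory peaks near 3.015 Hz (delta) and 22.11 Hz (beta), the spectral
#' signature used for the healthy class.
#'
#' @return A [spectral_class_profile()].
#' @export
healthy_profile <- function() {
  spectral_class_profile(
    peaks = data.frame(
      frequency = c(3.015, 22.11),
      amplitude = c(1.0, 0.8),
      bandwidth = c(0.5, 0.5)
    ),
    background_exponent = 1.0,
    noise_sd = 0.3,
    power_scale = 1.0
  )
}

#' Default MDD spectral profile
#'
#' A single dominant theta peak near 7.035 Hz and an overall power elevation
#' (`power_scale = 1.5`) relative to the healthy profile; the elevation
#' magnitude is configurable since only its direction is established.
#'
#' @return A [spectral_class_profile()].
#' @export
mdd_profile <- function() {
  spectral_class_profile(
    peaks = data.frame(
      frequency = 7.035,
      amplitude = 1.2,
      bandwidth = 0.5
    ),
    background_exponent = 1.0,
    noise_sd = 0.3,
    power_scale = 1.5
  )
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects_per_class Subjects per diagnostic class.
#' @param duration Recording duration per subject in seconds; `duration * fs`
#'   must be a whole number of samples.
#' @param fs Sampling rate in Hz (default 256).
#' @param n_channels Number of channels (default 20); must equal
#'   `length(channel_labels)`.
#' @param channel_labels Channel names; defaults to [default_montage()].
#' @param seed Integer master seed; per-subject seeds derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_class = 20L, duration = 60,
                        fs = 256, n_channels = 20L,
                        channel_labels = default_montage(), seed = 1L) {
  stop_if_not_scalar_number(n_subjects_per_class, "n_subjects_per_class", positive = TRUE)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  stop_if_not_scalar_number(fs, "fs", positive = TRUE)
  n_samples <- duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("`duration * fs` must be a whole number of samples", call. = FALSE)
  }
  if (length(channel_labels) != n_channels) {
    stop("`n_channels` must equal length(channel_labels)", call. = FALSE)
  }
  structure(
    list(
      n_subjects_per_class = as.integer(n_subjects_per_class),
      duration = duration,
      fs = fs,
      n_channels = as.integer(n_channels),
      channel_labels = as.character(channel_labels),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# 1/f^a background noise by spectral shaping of white Gaussian noise,
# rescaled to standard deviation `sd`.
one_over_f_noise <- function(n, exponent, sd) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  k <- seq_len(n) - 1L
  # two-sided frequency index; DC suppressed
  freq_idx <- pmin(k, n - k)
  shape <- c(0, freq_idx[-1]^(-exponent / 2))
  shaped <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  s <- stats::sd(shaped)
  if (s == 0) return(rep(0, n))
  shaped * (sd / s)
}

#' Generate one synthetic EEG recording
#'
#' The signal per channel is a sum of narrow-band sinusoids at the profile's
#' peak frequencies (independent uniform frequency jitter within each peak's
#' bandwidth and i.i.d. random phase per channel) plus 1/f^a background noise;
#' the whole channel is scaled by `sqrt(power_scale)`. Deterministic given
#' `seed`.
#'
#' @param profile A [spectral_class_profile()].
#' @param spec A [cohort_spec()]; supplies fs, duration, channels.
#' @param subject_id Subject identifier string.
#' @param class_label 0 (healthy) or 1 (MDD).
#' @param seed Integer seed for this recording.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(profile, spec, subject_id, class_label, seed) {
  stopifnot(inherits(profile, "spectral_class_profile"),
            inherits(spec, "cohort_spec"))
  nyquist <- spec$fs / 2
  bad <- profile$peaks$frequency >= nyquist
  if (any(bad)) {
    stop(sprintf(
      "peak frequency %.3f Hz is at or above the Nyquist frequency %.3f Hz",
      profile$peaks$frequency[which(bad)[1]], nyquist
    ), call. = FALSE)
  }
  n <- as.integer(round(spec$duration * spec$fs))
  t_sec <- (seq_len(n) - 1L) / spec$fs
  amp_scale <- sqrt(profile$power_scale)
  samples <- with_seed(seed, {
    out <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      x <- numeric(n)
      for (p in seq_len(nrow(profile$peaks))) {
        f0 <- profile$peaks$frequency[p]
        bw <- profile$peaks$bandwidth[p]
        a <- profile$peaks$amplitude[p]
        f <- f0 + stats::runif(1, -bw / 2, bw / 2)
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + a * sin(2 * pi * f * t_sec + phi)
      }
      x <- x + one_over_f_noise(n, profile$background_exponent, profile$noise_sd)
      out[ch, ] <- amp_scale * x
    }
    out
  })
  eeg_recording(samples, fs = spec$fs, channel_labels = spec$channel_labels,
                subject_id = subject_id, class_label = class_label)
}

#' Generate a two-class synthetic EEG cohort
#'
#' Produces `n_subjects_per_class` recordings per class with unique subject
#' ids (`H01..`, `M01..`), class labels 0 (healthy) and 1 (MDD), and
#' per-subject seeds derived deterministically from `spec$seed`.
#'
#' @param hg_profile Healthy-class [spectral_class_profile()].
#' @param mg_profile MDD-class [spectral_class_profile()].
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects, healthy first.
#' @export
generate_cohort <- function(hg_profile = healthy_profile(),
                            mg_profile = mdd_profile(),
                            spec = cohort_spec()) {
  n <- spec$n_subjects_per_class
  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    recs[[i]] <- generate_recording(
      hg_profile, spec, subject_id = sprintf("H%02d", i), class_label = 0L,
      seed = derive_seed(spec$seed, i)
    )
  }
  for (i in seq_len(n)) {
    recs[[n + i]] <- generate_recording(
      mg_profile, spec, subject_id = sprintf("M%02d", i), class_label = 1L,
      seed = derive_seed(spec$seed, n + i)
    )
  }
  recs
}
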