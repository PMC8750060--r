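#' Per-channel mean FFT power
#'
#' For each channel, the discrete Fourier transform of the n time samples is
#' taken and the squared magnitudes of the positive-frequency bins (DC
#' excluded, Nyquist included for even n) are averaged after scaling by
#' 1/n^2. A pure sinusoid of amplitude A at an exact bin frequency therefore
#' contributes A^2/4 to a single bin, so mean power scales with A^2.
#'
#' The DC bin is excluded because a constant voltage offset carries no rhythm
#' and would otherwise dominate the weights. Power is averaged over the full
#' 0-to-Nyquist range supported by the sampling rate.
#'
#' @param segment Channels x n numeric matrix (n >= 2) or a `tensor_segment`.
#' @param exclude_dc Drop the DC bin (default TRUE).
#' @return Numeric vector of per-channel mean power (microvolt^2).
#' @export
channel_mean_power <- function(segment, exclude_dc = TRUE) {
  if (inherits(segment, "tensor_segment")) segment <- from_tensor(segment)
  segment <- as.matrix(segment)
  n <- ncol(segment)
  if (n < 2L) stop("need at least 2 samples per channel", call. = FALSE)
  if (any(!is.finite(segment))) {
    stop("segment contains non-finite samples", call. = FALSE)
  }
  bins <- seq.int(2L, n %/% 2L + 1L)   # positive frequencies up to Nyquist
  if (!exclude_dc) bins <- c(1L, bins)
  apply(segment, 1, function(x) {
    p <- Mod(stats::fft(x))^2 / n^2
    mean(p[bins])
  })
}

#' Map channel powers to attention weights
#'
#' Min-max normalisation onto `[0.1, 1]`:
#' `w = 0.1 + 0.9 * (p - min(p)) / (max(p) - min(p))`. When all powers are
#' equal the map is undefined and every weight is set to 1 (the attention
#' block then leaves the segment unchanged).
#'
#' @param powers Non-negative per-channel mean powers.
#' @param range Two-element weight range, default `c(0.1, 1)`.
#' @return An object of class `attention_weights` with elements `weights`
#'   and `powers`.
#' @export
normalize_to_weights <- function(powers, range = c(0.1, 1)) {
  if (length(powers) < 1L || any(!is.finite(powers))) {
    stop("`powers` must be finite and non-empty", call. = FALSE)
  }
  if (any(powers < 0)) stop("`powers` must be non-negative", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  span <- max(powers) - min(powers)
  w <- if (span == 0) {
    rep(hi, length(powers))
  } else {
    lo + (hi - lo) * (powers - min(powers)) / span
  }
  structure(list(weights = w, powers = powers), class = "attention_weights")
}

#' Apply the frequency-attention block to one segment
#'
#' Each channel's a x b plane is multiplied elementwise by that channel's
#' scalar weight, computed from the same segment via [channel_mean_power()]
#' and [normalize_to_weights()]. The block has no learned parameters and is
#' deterministic. It is not idempotent: reapplying it recomputes weights on
#' the already-scaled data.
#'
#' @param ts A `tensor_segment`.
#' @param enabled If FALSE the block is the identity (ablation hook).
#' @param range Weight range passed to [normalize_to_weights()].
#' @param exclude_dc Passed to [channel_mean_power()].
#' @return A `tensor_segment` with scaled planes.
#' @export
apply_attention <- function(ts, enabled = TRUE, range = c(0.1, 1),
                            exclude_dc = TRUE) {
  stopifnot(inherits(ts, "tensor_segment"))
  if (!enabled) return(ts)
  p <- channel_mean_power(ts, exclude_dc = exclude_dc)
  w <- normalize_to_weights(p, range = range)$weights
  out <- ts
  out$tensor <- ts$tensor * w   # first array dim is channel: recycles by channel
  out
}
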