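#' ERB-rate conversion
#'
#' Map frequency in Hz to the equivalent-rectangular-bandwidth (ERB) rate
#' scale, an auditory scale approximating cochlear filter spacing, and back.
#'
#' @param f Frequency in Hz.
#' @param e ERB-rate value.
#' @return Numeric vector.
#' @export
hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Design a cochlear filterbank
#'
#' Builds a bank of `n_bands` zero-phase bandpass filters with half-cosine
#' frequency responses spaced on the ERB-rate scale, the standard simulated
#' cochlear decomposition used for analysing and resynthesising reverberant
#' impulse responses. Adjacent filters overlap so that the summed power
#' response is flat across `[f_lo, f_hi]`, which makes the decomposition
#' invertible (filter each subband a second time and sum).
#'
#' @param n_bands Number of bands (>= 1).
#' @param f_lo,f_hi Passband edges in Hz, `0 < f_lo < f_hi < sample_rate/2`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `cochlear_filterbank` with fields `n_bands`,
#'   `center_freqs` (Hz, strictly increasing), `band_edges` (Hz, the ERB-grid
#'   cutoffs), and `sample_rate`.
#' @examples
#' fb <- design_filterbank(32, 20, 10e3, 20e3)
#' fb$center_freqs[1:4]
#' @export
design_filterbank <- function(n_bands = 32, f_lo = 20, f_hi = 10e3,
                              sample_rate = 20e3) {
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 1) {
    abort("`n_bands` must be >= 1")
  }
  n_bands <- as.integer(n_bands)
  stopifnot_scalar_pos(f_lo, "f_lo")
  stopifnot_scalar_pos(f_hi, "f_hi")
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  if (!(f_lo < f_hi && f_hi <= sample_rate / 2)) {
    abort("require 0 < f_lo < f_hi <= sample_rate/2")
  }
  edges_erb <- seq(hz_to_erb(f_lo), hz_to_erb(f_hi), length.out = n_bands + 2L)
  centers <- erb_to_hz(edges_erb[2:(n_bands + 1L)])
  structure(
    list(
      n_bands = n_bands,
      center_freqs = centers,
      band_edges = erb_to_hz(edges_erb),
      edges_erb = edges_erb,
      f_lo = f_lo, f_hi = f_hi,
      sample_rate = sample_rate
    ),
    class = "cochlear_filterbank"
  )
}

#' @export
print.cochlear_filterbank <- function(x, ...) {
  cat(sprintf(
    "<cochlear_filterbank> %d bands, %.0f-%.0f Hz on ERB scale, fs = %.0f Hz\n",
    x$n_bands, x$f_lo, x$f_hi, x$sample_rate
  ))
  invisible(x)
}

# Frequency responses of all bands on the two-sided FFT grid of length n.
# Returns an n x n_bands matrix of real gains; squared gains sum to 1 inside
# [f_lo, f_hi] so decompose -> filter-again -> sum reconstructs the input.
filterbank_response <- function(fb, n) {
  freqs <- (seq_len(n) - 1) / n * fb$sample_rate
  freqs <- pmin(freqs, fb$sample_rate - freqs) # fold to [0, fs/2]
  e <- hz_to_erb(freqs)
  K <- fb$n_bands
  H <- matrix(0, n, K)
  if (K == 1L) {
    H[, 1] <- 1 # degenerate bank: an all-pass band covering [f_lo, f_hi]
  } else {
    cut <- fb$edges_erb
    for (k in seq_len(K)) {
      lo <- cut[k]; ce <- cut[k + 1]; hi <- cut[k + 2]
      up <- e >= lo & e < ce
      dn <- e >= ce & e <= hi
      H[up, k] <- sin(pi / 2 * (e[up] - lo) / (ce - lo))
      H[dn, k] <- cos(pi / 2 * (e[dn] - ce) / (hi - ce))
    }
    # low-pass / high-pass caps: the first band extends flat to DC and the
    # last to Nyquist. Sharp spectral edges at f_lo / f_hi would ring as
    # 1/t in time and bury decaying tails under the onset transient;
    # with the caps, adjacent cos/sin ramps sum to unit power everywhere.
    H[e < cut[2], 1] <- 1
    H[e > cut[K + 1], K] <- 1
  }
  H
}

#' Decompose a waveform into cochlear subbands
#'
#' @param waveform Numeric vector of audio samples.
#' @param fb A [design_filterbank()] object.
#' @return A `length(waveform) x n_bands` matrix of subband signals.
#' @export
subband_decompose <- function(waveform, fb) {
  stopifnot(inherits(fb, "cochlear_filterbank"))
  n <- length(waveform)
  # zero-pad to twice the length: FFT filtering is circular, and without
  # padding the filters' ringing wraps the signal onset into its tail,
  # which puts a spurious floor under decaying envelopes
  n2 <- 2L * n
  X <- fft(c(waveform, numeric(n)))
  H <- filterbank_response(fb, n2)
  out <- matrix(0, n, fb$n_bands)
  for (k in seq_len(fb$n_bands)) {
    out[, k] <- (Re(fft(X * H[, k], inverse = TRUE)) / n2)[seq_len(n)]
  }
  out
}

#' Reconstruct a waveform from its subband decomposition
#'
#' Applies each band filter a second time and sums across bands; because the
#' squared filter gains sum to one in the passband, this inverts
#' [subband_decompose()] for in-band signals.
#'
#' @param subbands Matrix from [subband_decompose()].
#' @param fb The filterbank used for analysis.
#' @return Numeric vector.
#' @export
subband_resynthesize <- function(subbands, fb) {
  stopifnot(inherits(fb, "cochlear_filterbank"))
  if (ncol(subbands) != fb$n_bands) abort("subband/filterbank mismatch")
  n <- nrow(subbands)
  n2 <- 2L * n
  H <- filterbank_response(fb, n2)
  acc <- numeric(n)
  for (k in seq_len(fb$n_bands)) {
    y <- Re(fft(fft(c(subbands[, k], numeric(n))) * H[, k],
                inverse = TRUE)) / n2
    acc <- acc + y[seq_len(n)]
  }
  acc
}

#' Subband amplitude envelopes
#'
#' Magnitude of the analytic signal in each cochlear band, lightly smoothed
#' with a moving-average window.
#'
#' @param waveform Numeric vector.
#' @param fb A [design_filterbank()] object; `sample_rate` must match the
#'   waveform's rate.
#' @param sample_rate Sampling rate of `waveform` in Hz (checked against `fb`).
#' @param smooth_ms Moving-average smoothing window in ms (0 disables).
#' @return A `length(waveform) x n_bands` matrix of nonnegative envelopes.
#' @export
subband_envelopes <- function(waveform, fb, sample_rate = fb$sample_rate,
                              smooth_ms = 10) {
  stopifnot(inherits(fb, "cochlear_filterbank"))
  if (!isTRUE(all.equal(sample_rate, fb$sample_rate))) {
    abort("waveform sample rate does not match the filterbank")
  }
  n <- length(waveform)
  n2 <- 2L * n
  X <- fft(c(waveform, numeric(n)))
  H <- filterbank_response(fb, n2)
  # analytic-signal mask: double positive frequencies, zero negatives
  an <- numeric(n2)
  an[1] <- 1
  an[2:(n2 / 2)] <- 2
  an[n2 / 2 + 1] <- 1
  env <- matrix(0, n, fb$n_bands)
  for (k in seq_len(fb$n_bands)) {
    env[, k] <- (Mod(fft(X * H[, k] * an, inverse = TRUE)) / n2)[seq_len(n)]
  }
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * fb$sample_rate))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      pad <- floor(w / 2)
      for (k in seq_len(fb$n_bands)) {
        x <- c(rep(env[1, k], pad), env[, k], rep(env[n, k], w - 1 - pad))
        env[, k] <- convolve(x, rev(kern), type = "filter")
      }
    }
  }
  pmax(env, 0)
}
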