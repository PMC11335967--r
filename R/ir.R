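#' Subband decay profile
#'
#' Per-band reverberation statistics of an impulse response: the RT60 (time
#' for band energy to fall by 60 dB) and initial level of each cochlear band,
#' plus the early-reflection cutoff that marks the start of the fitted
#' reverberant tail.
#'
#' @param band_rt60 Positive finite RT60 per band, seconds.
#' @param band_level_db Initial band level in dB (recycled).
#' @param early_cutoff Start of the reverberant tail, seconds after the
#'   direct-path peak.
#' @return A `subband_decay_profile` object.
#' @export
decay_profile <- function(band_rt60, band_level_db = 0, early_cutoff = 0.05) {
  if (any(!is.finite(band_rt60)) || any(band_rt60 <= 0)) {
    abort("all `band_rt60` must be positive and finite")
  }
  band_level_db <- rep_len(band_level_db, length(band_rt60))
  structure(
    list(
      band_rt60 = as.numeric(band_rt60),
      band_level_db = as.numeric(band_level_db),
      early_cutoff = early_cutoff
    ),
    class = "subband_decay_profile"
  )
}

#' @export
print.subband_decay_profile <- function(x, ...) {
  cat(sprintf(
    "<subband_decay_profile> %d bands, RT60 %.3f-%.3f s (median %.3f)\n",
    length(x$band_rt60), min(x$band_rt60), max(x$band_rt60),
    stats::median(x$band_rt60)
  ))
  invisible(x)
}

#' Real-world-like decay profile
#'
#' A parametric stand-in for the subband statistics of recorded room impulse
#' responses: RT60 decreases smoothly with frequency (low frequencies linger
#' longer, as in most real rooms) around a broadband target, and band levels
#' tilt gently downwards with frequency.
#'
#' @param fb A [design_filterbank()] object.
#' @param broadband_rt60 Target broadband RT60 in seconds.
#' @param spread Total log2 spread of band RT60s across the bank (the lowest
#'   band sits at `+spread/2` octaves relative to target, the highest at
#'   `-spread/2`).
#' @param tilt_db Level difference between the lowest and highest band, dB.
#' @param early_cutoff Early-reflection cutoff in seconds.
#' @return A [decay_profile()].
#' @export
real_profile <- function(fb, broadband_rt60 = 1.0686, spread = 0.4,
                         tilt_db = -9, early_cutoff = 0.05) {
  stopifnot(inherits(fb, "cochlear_filterbank"))
  K <- fb$n_bands
  g <- if (K == 1L) 0 else seq(spread / 2, -spread / 2, length.out = K)
  rt <- broadband_rt60 * 2^g
  lev <- if (K == 1L) 0 else seq(0, tilt_db, length.out = K)
  # calibrate so the *broadband* Schroeder RT60 (dominated by the slow,
  # loud bands late in the decay) hits the requested target
  for (i in 1:3) {
    rt <- rt * broadband_rt60 / predict_broadband_rt60(rt, lev)
  }
  decay_profile(band_rt60 = rt, band_level_db = lev,
                early_cutoff = early_cutoff)
}

# Broadband RT60 implied by a mixture of exponentially decaying bands:
# the Schroeder curve of sum_k L_k^2 10^(-6 t / rt_k) has the closed form
# sum_k L_k^2 rt_k 10^(-6 t / rt_k) (up to a constant); fit -5..-35 dB.
predict_broadband_rt60 <- function(band_rt60, band_level_db,
                                   fit_range = c(-5, -35)) {
  L2 <- 10^(band_level_db / 10)
  tt <- seq(0, 5 * max(band_rt60), by = max(band_rt60) / 500)
  edc <- vapply(tt, function(t) {
    sum(L2 * band_rt60 * 10^(-6 * t / band_rt60))
  }, numeric(1))
  edc_db <- 10 * log10(edc / edc[1])
  idx <- which(edc_db <= fit_range[1] & edc_db >= fit_range[2])
  fit <- lm(edc_db[idx] ~ tt[idx])
  -60 / coef(fit)[[2]]
}

ir_kinds <- c(
  "real_like", "ecological", "linear_decay", "time_reversed",
  "flat_spectral", "inverted_spectral"
)

#' Transform a decay profile into per-band amplitude envelopes
#'
#' Converts per-band reverberation statistics into amplitude envelopes on the
#' impulse-response time grid, applying one of the synthesis variants:
#'
#' * `ecological` (and `real_like`): exponential decay matching the profile
#'   unchanged.
#' * `linear_decay`: each band's amplitude falls linearly in time, reaching
#'   zero where its exponential envelope would reach -60 dB (at `t = RT60`).
#' * `time_reversed`: the ecological envelopes reversed in time.
#' * `flat_spectral`: all bands share the level-weighted mean decay rate, so
#'   every subband decays equally.
#' * `inverted_spectral`: decay rates are remapped onto a concave template
#'   peaking at mid bands (mean rate preserved, across-band spread preserved),
#'   so middle frequencies decay fastest.
#'
#' @param profile A [decay_profile()].
#' @param variant One of `r paste(ir_kinds, collapse = ", ")`.
#' @param ir_duration Envelope duration in seconds.
#' @param sample_rate Time-grid rate in Hz.
#' @return A `decay_envelope_set`: list with `env` (time x band matrix of
#'   nonnegative amplitudes), `shape_kind`, `variant`, `sample_rate`.
#' @export
transform_profile <- function(profile, variant, ir_duration = 2,
                              sample_rate = 20e3) {
  stopifnot(inherits(profile, "subband_decay_profile"))
  variant <- match.arg(variant, ir_kinds)
  stopifnot_scalar_pos(ir_duration, "ir_duration")
  n <- round(ir_duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  K <- length(profile$band_rt60)
  lev <- 10^(profile$band_level_db / 20)
  rate <- 60 / profile$band_rt60 # dB/s

  shape <- "exponential"
  rt <- profile$band_rt60
  if (variant == "flat_spectral") {
    rt <- rep(60 / stats::weighted.mean(rate, w = lev), K)
  } else if (variant == "inverted_spectral") {
    w <- sin(pi * (seq_len(K) - 0.5) / K) # concave, peaks mid-band
    if (K > 1 && sd(rate) > 0 && sd(w) > 0) {
      new_rate <- mean(rate) + (w - mean(w)) * sd(rate) / sd(w)
      new_rate <- pmax(new_rate, 60 / 8) # keep RT60 below 8 s
      rt <- 60 / new_rate
    }
  }

  if (variant == "linear_decay") {
    shape <- "linear"
    env <- sapply(seq_len(K), function(k) lev[k] * pmax(0, 1 - t / rt[k]))
  } else {
    # amplitude falls by 60 dB at t = RT60: lev * 10^(-3 t / RT60)
    env <- sapply(seq_len(K), function(k) lev[k] * 10^(-3 * t / rt[k]))
    if (variant == "time_reversed") {
      shape <- "reversed"
      env <- env[rev(seq_len(n)), , drop = FALSE]
    }
  }
  structure(
    list(env = env, shape_kind = shape, variant = variant,
         sample_rate = sample_rate),
    class = "decay_envelope_set"
  )
}

#' Reverse an envelope set in time
#'
#' @param envelopes A `decay_envelope_set`.
#' @return The envelope set with each band envelope reversed (an involution:
#'   applying it twice restores the input exactly).
#' @export
reverse_envelopes <- function(envelopes) {
  stopifnot(inherits(envelopes, "decay_envelope_set"))
  envelopes$env <- envelopes$env[rev(seq_len(nrow(envelopes$env))), ,
                                 drop = FALSE]
  envelopes$shape_kind <- if (envelopes$shape_kind == "reversed") {
    "exponential"
  } else {
    "reversed"
  }
  envelopes
}

#' Impulse-response container
#'
#' @param waveform Numeric samples.
#' @param sample_rate Hz.
#' @param kind Provenance label, one of
#'   `r paste(ir_kinds, collapse = ", ")`.
#' @param seed Integer seed used for the synthesis noise (or `NA`).
#' @return An `impulse_response` object.
#' @export
impulse_response <- function(waveform, sample_rate, kind = "real_like",
                             seed = NA_integer_) {
  if (any(!is.finite(waveform))) abort("impulse response samples must be finite")
  if (length(waveform) < 2) abort("impulse response must have positive duration")
  kind <- match.arg(kind, ir_kinds)
  structure(
    list(waveform = as.numeric(waveform), sample_rate = sample_rate,
         kind = kind, seed = seed),
    class = "impulse_response"
  )
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf(
    "<impulse_response> kind = %s, %.3f s @ %.0f Hz\n",
    x$kind, length(x$waveform) / x$sample_rate, x$sample_rate
  ))
  invisible(x)
}

#' Synthesize an impulse response from decay envelopes
#'
#' Filters seeded Gaussian noise into cochlear subbands, imposes the given
#' per-band amplitude envelope on each subband, and sums across bands.
#' Deterministic given `seed`.
#'
#' @param envelopes A `decay_envelope_set` from [transform_profile()].
#' @param fb The [design_filterbank()] whose band count matches the envelopes.
#' @param seed Integer RNG seed for the noise.
#' @param kind Provenance label recorded on the result; defaults to the
#'   envelope set's variant.
#' @return An [impulse_response()].
#' @export
synthesize_ir <- function(envelopes, fb, seed = 1L, kind = NULL) {
  stopifnot(inherits(envelopes, "decay_envelope_set"),
            inherits(fb, "cochlear_filterbank"))
  if (ncol(envelopes$env) != fb$n_bands) {
    abort("envelope set and filterbank band counts differ")
  }
  if (!isTRUE(all.equal(envelopes$sample_rate, fb$sample_rate))) {
    abort("envelope time grid and filterbank sample rates differ")
  }
  n <- nrow(envelopes$env)
  noise <- with_seed(seed, rnorm(n))
  sub <- subband_decompose(noise, fb)
  # normalise band noise power so the imposed envelope sets the band level
  scl <- sqrt(colMeans(sub^2))
  scl[scl < 1e-12] <- 1
  wav <- rowSums(sub * envelopes$env / rep(scl, each = n))
  impulse_response(
    wav, fb$sample_rate,
    kind = if (is.null(kind)) envelopes$variant else kind,
    seed = as.integer(seed)
  )
}

#' Synthesize a real-world-like impulse response
#'
#' Convenience wrapper: builds a [real_profile()] at a target broadband RT60
#' and synthesizes its exponential-decay realisation, labelled `real_like`.
#'
#' @inheritParams real_profile
#' @param fb A [design_filterbank()].
#' @param seed RNG seed.
#' @param duration IR duration in seconds.
#' @return An [impulse_response()].
#' @export
synth_real_ir <- function(fb, broadband_rt60 = 1.0686, seed = 1L,
                          duration = 2, spread = 0.4, tilt_db = -9) {
  prof <- real_profile(fb, broadband_rt60, spread = spread, tilt_db = tilt_db)
  env <- transform_profile(prof, "ecological", ir_duration = duration,
                           sample_rate = fb$sample_rate)
  synthesize_ir(env, fb, seed = seed, kind = "real_like")
}

# Schroeder backward integration of squared energy, in dB relative to the
# value at the start index.
schroeder_edc <- function(x2) {
  edc <- rev(cumsum(rev(x2)))
  10 * log10(pmax(edc / edc[1], 1e-30))
}

# Fit RT60 from an energy-decay curve sampled at `sample_rate`, using the
# -5..-35 dB region extrapolated to -60 dB. Returns list(rt60, valid, slope).
fit_rt60 <- function(edc_db, sample_rate, fit_range = c(-5, -35)) {
  idx <- which(edc_db <= fit_range[1] & edc_db >= fit_range[2])
  if (length(idx) < 5) {
    return(list(rt60 = NA_real_, valid = FALSE, slope = NA_real_))
  }
  tt <- (idx - 1) / sample_rate
  fit <- lm(edc_db[idx] ~ tt)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= -1e-9) {
    return(list(rt60 = NA_real_, valid = FALSE, slope = slope))
  }
  list(rt60 = -60 / slope, valid = TRUE, slope = slope)
}

#' Measure broadband RT60 of an impulse response
#'
#' Schroeder backward integration of the squared waveform after the
#' direct-path peak, with a linear fit to the -5 to -35 dB region of the
#' energy-decay curve extrapolated to -60 dB. Rising or non-decaying energy
#' is flagged as an invalid fit (`NA` with attribute `valid = FALSE`).
#'
#' @param ir An [impulse_response()] (or a numeric waveform).
#' @param sample_rate Required if `ir` is a bare numeric vector.
#' @return RT60 in seconds, with attributes `valid` (logical) and `slope`
#'   (dB/s of the fitted decay).
#' @examples
#' fs <- 8000
#' tau <- 0.145
#' ir <- impulse_response(exp(-(0:(2 * fs)) / fs / tau), fs)
#' measure_rt60(ir) # ~ 6.9078 * tau
#' @export
measure_rt60 <- function(ir, sample_rate = NULL) {
  if (inherits(ir, "impulse_response")) {
    x <- ir$waveform
    fs <- ir$sample_rate
  } else {
    x <- as.numeric(ir)
    if (is.null(sample_rate)) abort("`sample_rate` required for a bare waveform")
    fs <- sample_rate
  }
  peak <- which.max(abs(x))
  tail_x <- x[peak:length(x)]
  # guard: if most energy lies after a late "peak", energy is rising
  early_energy <- sum(x[seq_len(peak - 1)]^2)
  late_energy <- sum(tail_x^2)
  if (peak > length(x) / 2 && early_energy > 0.5 * late_energy) {
    out <- NA_real_
    attr(out, "valid") <- FALSE
    attr(out, "slope") <- NA_real_
    return(out)
  }
  edc <- schroeder_edc(tail_x^2)
  fit <- fit_rt60(edc, fs)
  out <- fit$rt60
  attr(out, "valid") <- fit$valid
  attr(out, "slope") <- fit$slope
  out
}

#' Estimate a subband decay profile from an impulse response
#'
#' Decomposes the IR into cochlear bands and fits each band's RT60 by
#' Schroeder backward integration of the band energy in the reverberant tail
#' (samples later than `early_cutoff` after the direct-path peak). Initial
#' band levels are taken as RMS band energy at the tail start. Bands whose
#' energy does not decay are flagged invalid (`NA` RT60).
#'
#' @param ir An [impulse_response()].
#' @param fb A [design_filterbank()] at the IR's sample rate.
#' @param early_cutoff Seconds after the direct-path peak to skip (early
#'   reflections are omitted from the fit).
#' @return A [decay_profile()] whose `band_rt60` may contain `NA` for
#'   invalid fits; attribute `valid` is `TRUE` when every band fit succeeded.
#' @export
estimate_decay_profile <- function(ir, fb, early_cutoff = 0.05) {
  stopifnot(inherits(ir, "impulse_response"), inherits(fb, "cochlear_filterbank"))
  if (!isTRUE(all.equal(ir$sample_rate, fb$sample_rate))) {
    abort("IR and filterbank sample rates differ")
  }
  n <- length(ir$waveform)
  if (n / ir$sample_rate <= early_cutoff) {
    abort("impulse response shorter than `early_cutoff`")
  }
  peak <- which.max(abs(ir$waveform))
  start <- min(peak + round(early_cutoff * ir$sample_rate), n - 10L)
  sub <- subband_decompose(ir$waveform, fb)
  rt60 <- lev_db <- numeric(fb$n_bands)
  ok <- logical(fb$n_bands)
  win <- max(1L, round(0.01 * ir$sample_rate))
  for (k in seq_len(fb$n_bands)) {
    tail_k <- sub[start:n, k]
    edc <- schroeder_edc(tail_k^2)
    fit <- fit_rt60(edc, ir$sample_rate)
    rt60[k] <- fit$rt60
    ok[k] <- fit$valid
    lev_db[k] <- 20 * log10(max(rms(tail_k[seq_len(win)]), 1e-15))
  }
  if (!any(ok)) {
    prof <- structure(
      list(band_rt60 = rt60, band_level_db = lev_db,
           early_cutoff = early_cutoff),
      class = "subband_decay_profile"
    )
  } else {
    safe <- rt60
    safe[!ok] <- stats::median(rt60[ok])
    prof <- decay_profile(safe, lev_db, early_cutoff)
    prof$band_rt60[!ok] <- NA_real_
  }
  attr(prof, "valid") <- all(ok)
  prof
}
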