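#' Generate a speech-like dry source
#'
#' A parametric stand-in for a dry speech recording: a harmonic complex
#' (plus a weak noise floor) amplitude-modulated at syllabic rates, so the
#' modulation spectrum of its envelope peaks in the 2-8 Hz range. The two
#' speaker attributes differ in fundamental-frequency band (A ~ 100-130 Hz,
#' B ~ 190-240 Hz).
#'
#' @param duration Seconds (> 0).
#' @param sample_rate Hz.
#' @param speaker_attr `"A"` or `"B"`.
#' @param source_id Identifier stored on the result.
#' @param seed RNG seed.
#' @return A [dry_source()].
#' @export
generate_dry_source <- function(duration = 3, sample_rate = 20e3,
                                speaker_attr = c("A", "B"),
                                source_id = NULL, seed = 1L) {
  speaker_attr <- match.arg(speaker_attr)
  stopifnot_scalar_pos(duration, "duration")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  with_seed(seed, {
    f0 <- if (speaker_attr == "A") runif(1, 100, 130) else runif(1, 190, 240)
    nh <- max(1L, floor(4000 / f0))
    carrier <- numeric(n)
    for (h in seq_len(nh)) {
      carrier <- carrier + sin(2 * pi * h * f0 * t + runif(1, 0, 2 * pi)) / h
    }
    carrier <- carrier + 0.05 * rnorm(n)
    # syllabic envelope: white noise bandpassed to 2-8 Hz in the FFT domain
    freqs <- (seq_len(n) - 1) / n * sample_rate
    freqs <- pmin(freqs, sample_rate - freqs)
    mask <- as.numeric(freqs >= 2 & freqs <= 8)
    mod <- Re(fft(fft(rnorm(n)) * mask, inverse = TRUE)) / n
    mod <- mod / max(abs(mod))
    env <- 1 + 0.9 * mod
    wav <- carrier * env
    wav <- wav / rms(wav) * 0.05
    dry_source(wav, sample_rate, speaker_attr,
               source_id = if (is.null(source_id)) {
                 sprintf("src_%s_%d", speaker_attr, seed)
               } else {
                 source_id
               })
  })
}

#' Generate a balanced pool of dry sources
#'
#' @param n Number of sources (speaker attributes alternate A/B, so even `n`
#'   gives an exactly balanced pool).
#' @inheritParams generate_dry_source
#' @return List of [dry_source()] objects with unique ids.
#' @export
generate_source_pool <- function(n, duration = 3, sample_rate = 20e3,
                                 seed = 1L) {
  lapply(seq_len(n), function(i) {
    generate_dry_source(
      duration, sample_rate,
      speaker_attr = if (i %% 2 == 1) "A" else "B",
      source_id = sprintf("src%04d", i),
      seed = child_seed(seed, i)
    )
  })
}

#' Condition-effect specification for simulated EEG
#'
#' Describes one class-contrast effect: a topography over channels, a time
#' window, an amplitude, and a per-subject lognormal amplitude jitter. In the
#' simulated epochs, trials of the first class receive `+amplitude/2` times
#' the topography times a raised-cosine bump over the window, and trials of
#' the second class receive the opposite sign.
#'
#' @param channels Channel names carrying the effect (weight 1; all other
#'   channels weight 0). Alternatively a named numeric vector of weights.
#' @param window_ms Length-2 numeric, effect window in ms.
#' @param amplitude Peak class-contrast amplitude in microvolts.
#' @param subject_sdlog Lognormal sigma of the per-subject amplitude jitter.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(channels, window_ms, amplitude = 1.5,
                        subject_sdlog = 0.2) {
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2]) {
    abort("`window_ms` must be an increasing length-2 interval")
  }
  weights <- if (is.numeric(channels)) {
    if (is.null(names(channels))) abort("numeric `channels` must be named")
    channels
  } else {
    stats::setNames(rep(1, length(channels)), channels)
  }
  if (any(!is.finite(weights))) abort("topography weights must be finite")
  structure(
    list(weights = weights, window_ms = as.numeric(window_ms),
         amplitude = amplitude, subject_sdlog = subject_sdlog),
    class = "effect_spec"
  )
}

#' Default condition effects
#'
#' The two-stage effect structure the simulator emulates: an early effect
#' (470-960 ms) over the bilateral temporal cluster and a late, perioffset
#' effect (2110-2500 ms) over the centroparietal cluster.
#'
#' @param layout Sensor layout used to resolve the preset clusters.
#' @param amplitude Peak contrast amplitude (microvolts) for both effects.
#' @return List of two [effect_spec()] objects (`early`, `late`).
#' @export
default_effects <- function(layout = sensor_layout_1020(), amplitude = 1.5) {
  cl <- preset_sensor_clusters(layout)
  list(
    early = effect_spec(cl$temporal, c(470, 960), amplitude),
    late = effect_spec(cl$centroparietal, c(2110, 2500), amplitude)
  )
}

#' Noise specification for simulated EEG
#'
#' Spatially correlated 1/f background plus independent white sensor noise:
#' the minimal realistic null for multichannel EEG.
#'
#' @param pink_sd Standard deviation of the 1/f background per channel, uV.
#' @param white_sd Standard deviation of the white sensor noise, uV.
#' @param exponent Spectral exponent of the background (power ~ 1/f^exponent).
#' @param spatial_scale Length scale (layout units) of the exponential
#'   channel-correlation kernel.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(pink_sd = 4, white_sd = 1, exponent = 1,
                       spatial_scale = 0.5) {
  if (pink_sd < 0 || white_sd < 0) abort("noise levels must be nonnegative")
  structure(
    list(pink_sd = pink_sd, white_sd = white_sd, exponent = exponent,
         spatial_scale = spatial_scale),
    class = "noise_spec"
  )
}

#' Simulate multichannel EEG epochs
#'
#' Generates trials x channels x time epochs at `sfreq` over
#' `epoch_ms[1]..epoch_ms[2]` ms: spatially correlated 1/f background noise
#' plus white sensor noise, plus, for every effect in `effects`, a
#' class-contingent spatiotemporal pattern (raised-cosine time course over
#' the effect window, the effect topography over channels, sign +/- by
#' class). Deterministic given `seed`.
#'
#' @param design Tibble with one row per trial; must contain the `class`
#'   column named by `class_col` (two levels; first level in sorted order
#'   gets the positive effect sign). All columns are carried into the epoch
#'   labels.
#' @param effects List of [effect_spec()] (possibly empty for null data).
#' @param noise A [noise_spec()].
#' @param layout Sensor layout tibble (`channel`, `x`, `y`).
#' @param seed RNG seed.
#' @param sfreq Sampling rate, Hz.
#' @param epoch_ms Epoch limits in ms relative to stimulus onset; the last
#'   sample falls `1000/sfreq` ms before `epoch_ms[2]`.
#' @param class_col Name of the class column in `design`.
#' @param subject_gain Multiplicative per-subject effect gain (draw once per
#'   subject, e.g. with [subject_gains()]).
#' @return An [epoch_set()] with `design` as labels.
#' @export
simulate_eeg_epochs <- function(design, effects = list(),
                                noise = noise_spec(),
                                layout = sensor_layout_1020(), seed = 1L,
                                sfreq = 1000, epoch_ms = c(-400, 2500),
                                class_col = "class", subject_gain = 1) {
  design <- tibble::as_tibble(design)
  n_tr <- nrow(design)
  if (!class_col %in% names(design)) {
    abort(sprintf("`design` lacks the '%s' column", class_col))
  }
  chans <- layout$channel
  n_ch <- length(chans)
  times <- seq(epoch_ms[1], epoch_ms[2] - 1000 / sfreq, by = 1000 / sfreq)
  n_t <- length(times)

  cls <- factor(design[[class_col]])
  if (nlevels(cls) != 2) abort("simulation requires exactly two class levels")
  sign_tr <- ifelse(as.integer(cls) == 1L, 0.5, -0.5)

  # spatial correlation factor: C = exp(-d / scale), data <- L %*% z
  xy <- as.matrix(layout[, c("x", "y")])
  D <- as.matrix(stats::dist(xy))
  L <- diag(n_ch)
  if (noise$spatial_scale > 0 && noise$pink_sd > 0) {
    C <- exp(-D / noise$spatial_scale)
    eig <- eigen(C, symmetric = TRUE)
    L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 1e-10))) %*% t(eig$vectors)
  }
  # 1/f amplitude shaping on the FFT grid
  freqs <- (seq_len(n_t) - 1) / n_t * sfreq
  freqs <- pmin(freqs, sfreq - freqs)
  shape <- ifelse(freqs > 0, freqs^(-noise$exponent / 2), 0)
  shape[1] <- 0

  # effect time courses and topographies
  eff_tc <- lapply(effects, function(e) {
    stopifnot(inherits(e, "effect_spec"))
    if (e$window_ms[1] < times[1] || e$window_ms[2] > times[n_t] + 1000 / sfreq) {
      abort("effect window lies outside the epoch")
    }
    inw <- times >= e$window_ms[1] & times <= e$window_ms[2]
    tc <- numeric(n_t)
    u <- (times[inw] - e$window_ms[1]) / diff(e$window_ms)
    tc[inw] <- 0.5 * (1 - cos(2 * pi * u)) # raised-cosine bump
    tc
  })
  eff_topo <- lapply(effects, function(e) {
    miss <- setdiff(names(e$weights), chans)
    if (length(miss)) {
      abort(paste("effect topography names unknown channels:",
                  paste(miss, collapse = ", ")))
    }
    w <- numeric(n_ch)
    w[match(names(e$weights), chans)] <- e$weights
    w
  })

  with_seed(seed, {
    amp <- vapply(effects, function(e) {
      e$amplitude * subject_gain * stats::rlnorm(1, 0, e$subject_sdlog)
    }, numeric(1))
    data <- array(0, dim = c(n_tr, n_ch, n_t))
    for (tr in seq_len(n_tr)) {
      pink <- matrix(0, n_t, n_ch)
      if (noise$pink_sd > 0) {
        W <- matrix(rnorm(n_t * n_ch), n_t, n_ch)
        pink <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / n_t
        pink <- scale(pink, center = FALSE,
                      scale = apply(pink, 2, sd) / noise$pink_sd)
        pink <- pink %*% L
      }
      x <- t(pink)
      if (noise$white_sd > 0) {
        x <- x + noise$white_sd * matrix(rnorm(n_ch * n_t), n_ch, n_t)
      }
      for (i in seq_along(effects)) {
        x <- x + sign_tr[tr] * amp[i] * outer(eff_topo[[i]], eff_tc[[i]])
      }
      data[tr, , ] <- x
    }
    epoch_set(data, times, chans, sfreq, labels = design)
  })
}

#' Per-subject effect gains
#'
#' @param n_subjects Number of subjects.
#' @param sdlog Lognormal sigma of the multiplicative gain.
#' @param seed RNG seed.
#' @return Numeric vector of gains (median 1).
#' @export
subject_gains <- function(n_subjects, sdlog = 0.2, seed = 1L) {
  with_seed(seed, stats::rlnorm(n_subjects, 0, sdlog))
}

#' Default per-variant probabilities of a correct realism judgment
#'
#' Behavioral emulation targets: real trials at 0.8195 and the five fake
#' variants graded from near-chance (ecological, flat spectral) to
#' near-ceiling (time reversed), averaging 0.6943 over fakes and 0.757
#' overall under the balanced design.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_p_correct <- function() {
  c(
    real = 0.8195, ecological = 0.52, linear_decay = 0.83,
    time_reversed = 0.96, flat_spectral = 0.55, inverted_spectral = 0.61
  )
}

#' Simulate behavioral reports
#'
#' Independent Bernoulli correctness per trial with a per-variant success
#' probability; the reported label equals the physical label when correct
#' and the opposite label otherwise.
#'
#' @param design Tibble with `class` (physical label, "real"/"fake") and
#'   `variant` columns.
#' @param p_correct Named probability vector over variants (names must cover
#'   all `design$variant` values; a `real_like` variant maps to `"real"`).
#' @param seed RNG seed.
#' @return `design` with added columns `correct` (logical) and `perceived`
#'   (reported class).
#' @export
simulate_behavior <- function(design, p_correct = default_p_correct(),
                              seed = 1L) {
  design <- tibble::as_tibble(design)
  key <- ifelse(design$variant %in% c("real_like", "real"), "real",
                as.character(design$variant))
  miss <- setdiff(unique(key), names(p_correct))
  if (length(miss)) {
    abort(paste("no p_correct for variant(s):", paste(miss, collapse = ", ")))
  }
  p <- unname(p_correct[key])
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  with_seed(seed, {
    correct <- rbinom(nrow(design), 1, p) == 1
    design$correct <- correct
    design$perceived <- ifelse(
      correct, as.character(design$class),
      ifelse(design$class == "real", "fake", "real")
    )
    design
  })
}

#' Build a balanced trial design table
#'
#' Convenience generator for simulation studies: `n_trials` trials split
#' half/half between real and fake classes, fake trials cycling through the
#' five synthetic variants, rooms cycling across trials, alternating speaker
#' attribute, random response location, and block numbers.
#'
#' @param n_trials Even trial count.
#' @param n_rooms Number of room identities to cycle.
#' @param n_blocks Number of blocks.
#' @param seed RNG seed (for response locations and row shuffling).
#' @return A tibble with columns `trial`, `class`, `variant`, `room_id`,
#'   `speaker_attr`, `response_location`, `block`.
#' @export
simulation_design <- function(n_trials = 60, n_rooms = 30, n_blocks = 10,
                              seed = 1L) {
  if (n_trials %% 2 != 0) abort("`n_trials` must be even")
  half <- n_trials / 2
  fake_variants <- c("ecological", "linear_decay", "time_reversed",
                     "flat_spectral", "inverted_spectral")
  des <- tibble::tibble(
    class = rep(c("real", "fake"), each = half),
    variant = c(rep("real_like", half),
                rep_len(fake_variants, half)),
    room_id = sprintf("room%02d", rep_len(seq_len(n_rooms), n_trials)),
    speaker_attr = rep_len(c("A", "B"), n_trials)
  )
  with_seed(seed, {
    des <- des[sample(n_trials), ]
    des$trial <- seq_len(n_trials)
    # near-equal counts per location, as in the counterbalanced response array
    des$response_location <- sample(rep_len(1:8, n_trials))
    des$block <- rep(seq_len(n_blocks), each = ceiling(n_trials / n_blocks),
                     length.out = n_trials)
    dplyr::relocate(des, "trial")
  })
}
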