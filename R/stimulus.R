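#' Dry source container
#'
#' @param waveform Numeric audio samples.
#' @param sample_rate Hz.
#' @param speaker_attr Speaker attribute, `"A"` or `"B"` (stands in for the
#'   two speaker genders of a balanced speech corpus).
#' @param source_id Unique identifier.
#' @return A `dry_source` object.
#' @export
dry_source <- function(waveform, sample_rate, speaker_attr = c("A", "B"),
                       source_id = "src1") {
  speaker_attr <- match.arg(speaker_attr)
  if (any(!is.finite(waveform))) abort("dry source samples must be finite")
  structure(
    list(waveform = as.numeric(waveform), sample_rate = sample_rate,
         speaker_attr = speaker_attr, source_id = source_id),
    class = "dry_source"
  )
}

#' Convolve a dry source with an impulse response and cut a 2 s stimulus
#'
#' Full linear convolution of source and IR, followed by the standard
#' stimulus dressing: locate the maximal-amplitude sample within the first
#' 1000 ms of the convolved sound, extract the 2 s segment yoked to that peak
#' (starting `peak_lead` seconds before it, clipped at the signal start),
#' apply 5 ms raised-cosine on/off ramps, and scale to the reference RMS.
#' Ramping precedes RMS scaling so the equalisation is exact.
#'
#' @param source A [dry_source()].
#' @param ir An [impulse_response()] at the same sample rate.
#' @param ref_rms Reference root-mean-square amplitude for equalisation.
#' @param duration Segment duration in seconds (2 by default).
#' @param peak_window Window (seconds from convolution start) in which the
#'   yoking peak is searched.
#' @param peak_lead Segment start offset before the peak, seconds.
#' @param ramp_ms Raised-cosine ramp duration, ms.
#' @return A `stimulus` object: `waveform`, `sample_rate`, `rms`, and
#'   metadata fields (`class`, `variant`, `ir_id`, `source_id`,
#'   `speaker_attr`).
#' @export
convolve_and_segment <- function(source, ir, ref_rms = 0.1, duration = 2,
                                 peak_window = 1, peak_lead = 0.1,
                                 ramp_ms = 5) {
  stopifnot(inherits(source, "dry_source"), inherits(ir, "impulse_response"))
  if (!isTRUE(all.equal(source$sample_rate, ir$sample_rate))) {
    abort("source and IR sample rates differ")
  }
  fs <- source$sample_rate
  conv <- convolve(source$waveform, rev(ir$waveform), type = "open")
  nseg <- round(duration * fs)
  if (length(conv) < nseg) abort("convolved sound is shorter than the segment")
  peak_idx <- which.max(abs(conv[seq_len(min(round(peak_window * fs),
                                             length(conv)))]))
  start <- max(1L, peak_idx - round(peak_lead * fs))
  if (start + nseg - 1L > length(conv)) {
    abort("convolved sound too short for a peak-yoked segment")
  }
  seg <- conv[start:(start + nseg - 1L)]
  nr <- round(ramp_ms / 1000 * fs)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr)) # starts exactly at 0
  seg[seq_len(nr)] <- seg[seq_len(nr)] * ramp
  seg[nseg - seq_len(nr) + 1L] <- seg[nseg - seq_len(nr) + 1L] * ramp
  seg <- seg * (ref_rms / rms(seg))
  structure(
    list(
      waveform = seg, sample_rate = fs, rms = rms(seg),
      class = if (ir$kind == "real_like") "real" else "fake",
      variant = ir$kind, ir_id = NA_character_,
      source_id = source$source_id, speaker_attr = source$speaker_attr
    ),
    class = "stimulus"
  )
}

#' Build the balanced stimulus set
#'
#' Synthesizes, for each real-world-like decay profile, one `real_like` IR
#' and one IR per synthetic variant, convolves each IR with unique dry
#' sources, and segments/equalises the results. The default preset mirrors a
#' 600-stimulus design: 30 profiles x (10 sources through the real IR + 2
#' sources through each of 5 variants), i.e. 300 real and 300 fake stimuli,
#' every source used exactly once and speaker attributes balanced overall.
#'
#' @param profiles List of [decay_profile()] objects (one per "room").
#' @param sources List of [dry_source()] objects; must contain at least
#'   `length(profiles) * (n_real_sources + n_variant_sources * length(variants))`
#'   unique sources.
#' @param fb [design_filterbank()] at the sources' sample rate.
#' @param variants Character vector of synthetic variants.
#' @param n_real_sources Sources convolved with each real IR.
#' @param n_variant_sources Sources convolved with each variant IR.
#' @param ref_rms Reference RMS for equalisation.
#' @param ir_duration IR duration, seconds.
#' @param seed Seed controlling IR synthesis noise and source assignment.
#' @param keep_waveforms Keep stimulus waveforms (set `FALSE` to return the
#'   manifest only, saving memory).
#' @return A `stimulus_set`: list with `manifest` (a tibble with one row per
#'   stimulus: `stimulus_id`, `class`, `variant`, `ir_id`, `source_id`,
#'   `speaker_attr`, `duration`, `rms`), `waveforms` (named list or `NULL`),
#'   `sample_rate`, `ref_rms`, `seed`.
#' @export
build_stimulus_set <- function(profiles, sources, fb,
                               variants = c("ecological", "linear_decay",
                                            "time_reversed", "flat_spectral",
                                            "inverted_spectral"),
                               n_real_sources = 10, n_variant_sources = 2,
                               ref_rms = 0.1, ir_duration = 2, seed = 1L,
                               keep_waveforms = TRUE) {
  stopifnot(inherits(fb, "cochlear_filterbank"))
  n_per_room <- n_real_sources + n_variant_sources * length(variants)
  need <- length(profiles) * n_per_room
  ids <- vapply(sources, function(s) s$source_id, character(1))
  if (anyDuplicated(ids)) abort("source ids must be unique")
  if (length(sources) < need) {
    abort(sprintf("need %d unique sources, got %d", need, length(sources)))
  }
  # draw sources alternately from the two speaker pools so the speaker
  # attribute is balanced within every class by construction
  attrs <- vapply(sources, function(s) s$speaker_attr, character(1))
  shuffle <- function(x) x[sample.int(length(x))]
  pool <- with_seed(child_seed(seed, 0L), list(
    A = shuffle(which(attrs == "A")), B = shuffle(which(attrs == "B"))
  ))
  ptr <- c(A = 0L, B = 0L)
  next_sources <- function(k) {
    take_a <- ceiling(k / 2)
    # alternate which pool gets the odd pick so totals stay balanced
    if (k %% 2 == 1 && (ptr[["A"]] > ptr[["B"]])) take_a <- k - take_a
    picks <- c(pool$A[ptr[["A"]] + seq_len(take_a)],
               pool$B[ptr[["B"]] + seq_len(k - take_a)])
    if (anyNA(picks)) abort("source pool exhausted or speaker-unbalanced")
    ptr[["A"]] <<- ptr[["A"]] + take_a
    ptr[["B"]] <<- ptr[["B"]] + (k - take_a)
    sources[picks]
  }

  rows <- list()
  waves <- list()
  sid <- 0L
  for (p in seq_along(profiles)) {
    room <- sprintf("room%02d", p)
    irs <- c(
      list(real_like = synthesize_ir(
        transform_profile(profiles[[p]], "ecological", ir_duration,
                          fb$sample_rate),
        fb, seed = child_seed(seed, p * 100L), kind = "real_like"
      )),
      stats::setNames(lapply(seq_along(variants), function(v) {
        synthesize_ir(
          transform_profile(profiles[[p]], variants[v], ir_duration,
                            fb$sample_rate),
          fb, seed = child_seed(seed, p * 100L + v)
        )
      }), variants)
    )
    for (kind in names(irs)) {
      k <- if (kind == "real_like") n_real_sources else n_variant_sources
      for (s in next_sources(k)) {
        sid <- sid + 1L
        st <- convolve_and_segment(s, irs[[kind]], ref_rms = ref_rms)
        st$ir_id <- room
        stim_id <- sprintf("stim%04d", sid)
        rows[[sid]] <- tibble::tibble(
          stimulus_id = stim_id, class = st$class, variant = st$variant,
          ir_id = room, source_id = s$source_id,
          speaker_attr = s$speaker_attr,
          duration = length(st$waveform) / st$sample_rate, rms = st$rms
        )
        if (keep_waveforms) waves[[stim_id]] <- st$waveform
      }
    }
  }
  structure(
    list(
      manifest = dplyr::bind_rows(rows),
      waveforms = if (keep_waveforms) waves else NULL,
      sample_rate = fb$sample_rate, ref_rms = ref_rms, seed = seed
    ),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "<stimulus_set> %d stimuli (%d real / %d fake) @ %.0f Hz\n",
    nrow(x$manifest), sum(x$manifest$class == "real"),
    sum(x$manifest$class == "fake"), x$sample_rate
  ))
  invisible(x)
}

#' Schedule stimuli into counterbalanced blocks
#'
#' Randomly assigns stimuli to `n_blocks` blocks of `trials_per_block` trials
#' such that every block holds equally many real and fake stimuli, then
#' shuffles order within block. Optionally adds a per-trial intensity jitter
#' (`gain_db`, uniform in `+/- jitter_db`) applied at presentation time.
#'
#' @param set A `stimulus_set` (or its manifest tibble with `stimulus_id` and
#'   `class` columns).
#' @param n_blocks,trials_per_block Block structure; their product must equal
#'   the stimulus count and `trials_per_block` must be even.
#' @param jitter_db Half-range of the per-trial intensity jitter in dB.
#' @param seed RNG seed.
#' @return A tibble (`trial_schedule`): one row per trial with `block`,
#'   `trial`, `stimulus_id`, `class`, plus manifest metadata and `gain_db`.
#' @export
schedule_blocks <- function(set, n_blocks = 10, trials_per_block = 60,
                            jitter_db = 1, seed = 1L) {
  manifest <- if (inherits(set, "stimulus_set")) set$manifest else set
  n <- nrow(manifest)
  if (n_blocks * trials_per_block != n) {
    abort("n_blocks * trials_per_block must equal the stimulus count")
  }
  if (trials_per_block %% 2 != 0) abort("trials_per_block must be even")
  idx_real <- which(manifest$class == "real")
  idx_fake <- which(manifest$class == "fake")
  if (length(idx_real) != length(idx_fake)) {
    abort("schedule requires equally many real and fake stimuli")
  }
  half <- trials_per_block / 2
  with_seed(seed, {
    idx_real <- sample(idx_real)
    idx_fake <- sample(idx_fake)
    out <- lapply(seq_len(n_blocks), function(b) {
      rows <- c(idx_real[(b - 1) * half + seq_len(half)],
                idx_fake[(b - 1) * half + seq_len(half)])
      rows <- sample(rows)
      dplyr::mutate(manifest[rows, ], block = b,
                    trial = (b - 1) * trials_per_block + dplyr::row_number(),
                    .before = 1)
    })
    sched <- dplyr::bind_rows(out)
    sched$gain_db <- runif(n, -jitter_db, jitter_db)
    sched
  })
}
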