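#' Re-reference epochs to the common average
#'
#' Subtracts, at every trial and time point, the instantaneous mean over
#' channels, so the channel mean is zero everywhere. Idempotent.
#'
#' @param epochs An [epoch_set()] with at least two channels.
#' @return An [epoch_set()].
#' @export
rereference_common_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2] < 2) abort("common-average reference requires >= 2 channels")
  m <- apply(epochs$data, c(1, 3), mean) # trials x time
  epochs$data <- epochs$data - aperm(
    array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2)
  )
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window, so
#' the within-window mean is zero. Idempotent; invariant to per-channel
#' constant offsets.
#'
#' @param epochs An [epoch_set()].
#' @param window Length-2 ms interval (inclusive) within the epoch.
#' @return An [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) abort("baseline window lies outside the epoch")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(base, dim = dim(epochs$data))
  epochs
}

#' Downsample epochs by boxcar averaging
#'
#' Averages nonoverlapping `bin_ms` windows; each output sample is the mean
#' of its bin and is timestamped at the bin's left edge, so a 1000 Hz epoch
#' spanning -400..2500 ms with 10 ms bins yields 290 samples at -400, -390,
#' ..., 2490 ms.
#'
#' @param epochs An [epoch_set()].
#' @param bin_ms Bin width in ms; the bin length in samples must divide the
#'   epoch length.
#' @return An [epoch_set()] at rate `1000 / bin_ms` Hz.
#' @export
downsample_boxcar <- function(epochs, bin_ms = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  nb <- bin_ms / 1000 * epochs$sfreq
  if (abs(nb - round(nb)) > 1e-9) abort("bin must be an integer number of samples")
  nb <- as.integer(round(nb))
  d <- dim(epochs$data)
  if (d[3] %% nb != 0) abort("bin length must divide the epoch length")
  n_out <- d[3] %/% nb
  dim(epochs$data) <- c(d[1] * d[2], nb, n_out)
  out <- apply(epochs$data, c(1, 3), mean)
  dim(out) <- c(d[1], d[2], n_out)
  epoch_set(out, epochs$times[seq(1, d[3], by = nb)], epochs$channels,
            1000 / bin_ms, epochs$labels)
}

#' Low-pass filter epochs
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass along the
#' time axis of every trial and channel.
#'
#' @param epochs An [epoch_set()].
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist rate.
#' @param order Butterworth order (applied twice by filtering both ways).
#' @return An [epoch_set()].
#' @export
lowpass_epochs <- function(epochs, cutoff = 30, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sfreq / 2
  if (cutoff >= nyq) abort("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  d <- dim(epochs$data)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      epochs$data[tr, ch, ] <- signal::filtfilt(bf, epochs$data[tr, ch, ])
    }
  }
  epochs
}

#' Standard preprocessing chain
#'
#' Common-average re-reference, baseline correction, 10 ms boxcar
#' downsampling, then a 30 Hz zero-phase low-pass (filtering after
#' downsampling, matching the analysis convention this pipeline follows).
#'
#' @param epochs An [epoch_set()] at acquisition rate.
#' @param baseline Baseline window, ms.
#' @param bin_ms Downsampling bin, ms.
#' @param cutoff Low-pass cutoff, Hz.
#' @return A preprocessed [epoch_set()].
#' @export
preprocess_epochs <- function(epochs, baseline = c(-200, 0), bin_ms = 10,
                              cutoff = 30) {
  epochs |>
    rereference_common_average() |>
    baseline_correct(baseline) |>
    downsample_boxcar(bin_ms) |>
    lowpass_epochs(cutoff)
}

label_schemes <- c(
  "physical", "perceived", "correct_only", "incorrect_only",
  "variant_vs_real", "room_id", "speaker_attr", "response_location",
  "block_half"
)

#' Label trials for a decoding analysis
#'
#' Maps the per-trial label table onto the class assignment a given analysis
#' needs, together with the trial mask of included trials:
#'
#' * `physical`: real vs fake stimulus class, all trials.
#' * `perceived`: reported class, all trials.
#' * `correct_only` / `incorrect_only`: physical class on the behaviorally
#'   correct (incorrect) trials only.
#' * `variant_vs_real`: physical class restricted to real trials plus one
#'   fake `variant`.
#' * `room_id`, `speaker_attr`, `response_location`: control relabelings by
#'   stimulus/response attributes orthogonal to the realism manipulation.
#' * `block_half`: first half vs last half of blocks.
#'
#' @param epochs An [epoch_set()] whose labels contain the needed columns.
#' @param scheme One of `r paste(label_schemes, collapse = ", ")`.
#' @param variant Fake variant for `variant_vs_real`.
#' @return A tibble with columns `trial` (index into `epochs`) and `class`
#'   (factor); attribute `counts` holds the per-class trial counts.
#' @export
label_trials <- function(epochs, scheme = "physical", variant = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  scheme <- match.arg(scheme, label_schemes)
  lb <- epochs$labels
  need <- switch(scheme,
    physical = "class",
    perceived = "perceived",
    correct_only = c("class", "correct"),
    incorrect_only = c("class", "correct"),
    variant_vs_real = c("class", "variant"),
    room_id = "room_id",
    speaker_attr = "speaker_attr",
    response_location = "response_location",
    block_half = "block"
  )
  miss <- setdiff(need, names(lb))
  if (length(miss)) {
    abort(paste("labels lack column(s):", paste(miss, collapse = ", ")))
  }
  n <- nrow(lb)
  idx <- seq_len(n)
  y <- switch(scheme,
    physical = lb$class,
    perceived = lb$perceived,
    correct_only = {
      idx <- which(lb$correct)
      lb$class[idx]
    },
    incorrect_only = {
      idx <- which(!lb$correct)
      lb$class[idx]
    },
    variant_vs_real = {
      if (is.null(variant)) abort("`variant` required for variant_vs_real")
      idx <- which(lb$class == "real" | lb$variant == variant)
      lb$class[idx]
    },
    room_id = lb$room_id,
    speaker_attr = lb$speaker_attr,
    response_location = lb$response_location,
    block_half = {
      cut <- stats::median(unique(lb$block))
      ifelse(lb$block <= cut, "first_half", "last_half")
    }
  )
  out <- tibble::tibble(trial = idx, class = factor(y))
  attr(out, "counts") <- table(out$class)
  attr(out, "scheme") <- scheme
  out
}
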