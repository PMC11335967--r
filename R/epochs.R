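#' Epoched EEG container
#'
#' A light container for epoched multichannel EEG: a trials x channels x time
#' array (microvolts), a monotonic time axis in ms relative to stimulus
#' onset, channel names, the sampling rate, and a per-trial label table.
#'
#' @param data Numeric array, trials x channels x time.
#' @param times Numeric vector of sample times in ms (length = dim 3).
#' @param channels Unique channel names (length = dim 2).
#' @param sfreq Sampling rate in Hz.
#' @param labels Tibble with one row per trial; typical columns: `class`
#'   (physical label), `perceived`, `correct`, `variant`, `room_id`,
#'   `speaker_attr`, `response_location`, `block`.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, times, channels, sfreq, labels = NULL) {
  d <- dim(data)
  if (length(d) != 3) abort("`data` must be a 3-d array (trials x channels x time)")
  if (length(times) != d[3]) abort("`times` length must match time dimension")
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing")
  if (length(channels) != d[2]) abort("`channels` length must match channel dimension")
  if (anyDuplicated(channels)) abort("channel names must be unique")
  if (is.null(labels)) labels <- tibble::tibble(.rows = d[1])
  if (nrow(labels) != d[1]) abort("`labels` must have one row per trial")
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, times = as.numeric(times), channels = channels,
         sfreq = sfreq, labels = labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples, %.0f Hz, %.0f..%.0f ms\n",
    d[1], d[2], d[3], x$sfreq, x$times[1], x$times[length(x$times)]
  ))
  if (ncol(x$labels)) {
    cat("labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset an epoch set
#'
#' @param epochs An [epoch_set()].
#' @param trials Integer/logical trial selector (optional).
#' @param channels Channel-name or index selector (optional).
#' @return An [epoch_set()].
#' @export
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  tr <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else trials
  ch <- if (is.null(channels)) {
    seq_len(dim(epochs$data)[2])
  } else if (is.character(channels)) {
    miss <- setdiff(channels, epochs$channels)
    if (length(miss)) abort(paste("unknown channels:", paste(miss, collapse = ", ")))
    match(channels, epochs$channels)
  } else {
    channels
  }
  epoch_set(
    epochs$data[tr, ch, , drop = FALSE], epochs$times,
    epochs$channels[ch], epochs$sfreq, epochs$labels[tr, , drop = FALSE]
  )
}

#' Write / read an epoch container
#'
#' On-disk format: a little-endian 32-bit float binary array (trial-major:
#' the full channels x time matrix of trial 1, then trial 2, ...) next to a
#' JSON sidecar holding dimensions, channel names, time axis, sampling rate,
#' the label table and free-form provenance. `read_epochs(write_epochs(x))`
#' round-trips bit-exactly at float32 precision.
#'
#' @param epochs An [epoch_set()].
#' @param path Path of the binary file; the sidecar is `paste0(path, ".json")`.
#' @param provenance Optional named list stored in the sidecar.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   [epoch_set()] with attribute `provenance`.
#' @export
write_epochs <- function(epochs, path, provenance = list()) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  side <- list(
    dims = d, channels = epochs$channels, times = epochs$times,
    sfreq = epochs$sfreq, labels = epochs$labels, provenance = provenance
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(raw) != n) abort("epoch container truncated: sidecar dims mismatch")
  data <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  labels <- tibble::as_tibble(side$labels)
  if (nrow(labels) == 0 && d[1] > 0) labels <- tibble::tibble(.rows = d[1])
  out <- epoch_set(data, side$times, side$channels, side$sfreq, labels)
  attr(out, "provenance") <- side$provenance
  out
}
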