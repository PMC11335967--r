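#' Stack a retrospective sliding window into feature vectors
#'
#' For decoded time index `t`, features are the sensor patterns at samples
#' `t - lookback .. t` stacked into one composite vector per trial. Ordering
#' is channel-major by time: all channels at `t - lookback`, then all
#' channels at the next sample, and so on (fixed and documented, so stacked
#' features are comparable across calls).
#'
#' @param epochs An [epoch_set()].
#' @param t_index 1-based time index; must satisfy `t_index > lookback`.
#' @param lookback Window length in samples before `t` (window includes both
#'   endpoints, so 20 gives 21 samples).
#' @return A trials x (channels * (lookback + 1)) matrix.
#' @examples
#' # 63 channels and a 20-sample lookback give 63 * 21 = 1323 features
#' @export
stack_window <- function(epochs, t_index, lookback = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (lookback < 0) abort("`lookback` must be >= 0")
  d <- dim(epochs$data)
  if (t_index <= lookback || t_index > d[3]) {
    abort("`t_index` must satisfy lookback < t_index <= n_times")
  }
  w <- (t_index - lookback):t_index
  out <- epochs$data[, , w, drop = FALSE]
  dim(out) <- c(d[1], d[2] * length(w))
  out
}

#' Form pseudo-trials by subaveraging
#'
#' Randomly assigns the trials of one class to `n_subsets` near-equal
#' subsets and averages within each, yielding `n_subsets` pseudo-trials with
#' boosted signal-to-noise ratio. With equal subset sizes the pseudo-trial
#' mean equals the trial mean exactly.
#'
#' @param x Trials x ... array (matrix or 3-d array); trials on dim 1.
#' @param n_subsets Number of pseudo-trials to form; requires at least this
#'   many trials.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return Array like `x` with `n_subsets` rows.
#' @export
make_subaverages <- function(x, n_subsets = 10, seed = NULL) {
  d <- dim(x)
  if (is.null(d)) {
    x <- matrix(x, ncol = 1)
    d <- dim(x)
  }
  n <- d[1]
  if (n < n_subsets) {
    abort(sprintf("need at least %d trials to form %d subaverages",
                  n_subsets, n_subsets))
  }
  assign <- with_seed(seed, rep_len(seq_len(n_subsets), n)[sample(n)])
  flat <- x
  dim(flat) <- c(n, prod(d[-1]))
  means <- rowsum(flat, assign) / as.vector(table(assign))
  dim(means) <- c(n_subsets, d[-1])
  means
}

# normalise the `labels` argument of the decoding functions into a
# tibble(trial, class)
resolve_labels <- function(epochs, labels, variant = NULL) {
  if (is.character(labels) && length(labels) == 1L) {
    label_trials(epochs, labels, variant = variant)
  } else if (is.data.frame(labels)) {
    tibble::tibble(trial = labels$trial, class = factor(labels$class))
  } else {
    tibble::tibble(trial = seq_along(labels), class = factor(labels))
  }
}

# Binary decoding engine shared by the time-course and TGM front ends.
# Returns nt x nt accuracy (proportion) matrix if tgm, else length-nt vector.
decode_engine <- function(X, idx1, idx2, t_idx, lookback, n_subsets, n_perm,
                          cost, standardize, seed, tgm = FALSE) {
  d <- dim(X)
  nt <- length(t_idx)
  L1 <- lookback + 1L
  acc <- if (tgm) matrix(0, nt, nt) else numeric(nt)
  perm_seeds <- vapply(seq_len(n_perm), function(p) child_seed(seed, p),
                       integer(1))
  for (p in seq_len(n_perm)) {
    P1 <- make_subaverages(X[idx1, , , drop = FALSE], n_subsets,
                           seed = perm_seeds[p])
    P2 <- make_subaverages(X[idx2, , , drop = FALSE], n_subsets,
                           seed = child_seed(perm_seeds[p], 7919L))
    P <- array(0, dim = c(2L * n_subsets, d[2], d[3]))
    P[seq_len(n_subsets), , ] <- P1
    P[n_subsets + seq_len(n_subsets), , ] <- P2
    if (tgm) {
      FF <- matrix(0, 2L * n_subsets, nt * d[2] * L1)
      for (i in seq_len(nt)) {
        blk <- P[, , (t_idx[i] - lookback):t_idx[i], drop = FALSE]
        dim(blk) <- c(2L * n_subsets, d[2] * L1)
        FF[, (i - 1L) * d[2] * L1 + seq_len(d[2] * L1)] <- blk
      }
      acc <- acc + .cpp_tgm(FF, nt, cost, standardize)
    } else {
      for (i in seq_len(nt)) {
        blk <- P[, , (t_idx[i] - lookback):t_idx[i], drop = FALSE]
        dim(blk) <- c(2L * n_subsets, d[2] * L1)
        acc[i] <- acc[i] + .cpp_cv_accuracy(blk, cost, standardize)
      }
    }
  }
  acc / n_perm
}

# shared front-end validation; returns list of per-pair index sets
decode_prepare <- function(epochs, labels, variant, lookback, stride,
                           n_subsets) {
  lab <- resolve_labels(epochs, labels, variant)
  classes <- levels(lab$class)
  if (length(classes) < 2) abort("decoding requires at least two classes")
  counts <- table(lab$class)
  if (any(counts < n_subsets)) {
    abort(sprintf(
      "every class needs >= n_subsets (%d) trials; smallest has %d",
      n_subsets, min(counts)
    ))
  }
  d <- dim(epochs$data)
  t_idx <- seq(lookback + 1L, d[3], by = stride)
  if (!length(t_idx)) abort("epoch shorter than the retrospective window")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  idx <- lapply(classes, function(cl) lab$trial[lab$class == cl])
  names(idx) <- classes
  list(lab = lab, classes = classes, pairs = pairs, idx = idx, t_idx = t_idx)
}

#' Retrospective sliding-window decoding time course
#'
#' For every decoded time point `t`, trials of each class are randomly
#' subaveraged into `n_subsets` pseudo-trials; a linear support-vector
#' classifier (regularisation constant `cost`, features z-scored with
#' training-fold statistics) is trained on the stacked `[t - lookback, t]`
#' window and evaluated by leave-one-pseudo-trial-per-class-out
#' cross-validation; the procedure is repeated for `n_perm` fresh subaverage
#' assignments and averaged. With more than two classes, all pairwise binary
#' decodings are run and their accuracies averaged (one-vs-one), so chance
#' remains 50%.
#'
#' @param epochs A preprocessed [epoch_set()].
#' @param labels A labeling scheme name (see [label_trials()]), a
#'   tibble(`trial`, `class`), or a per-trial factor.
#' @param variant Fake variant when `labels = "variant_vs_real"`.
#' @param lookback Retrospective window length in samples (window spans
#'   `lookback + 1` samples including both endpoints).
#' @param stride Decode every `stride`-th time point.
#' @param n_subsets Pseudo-trials per class (also the number of CV folds).
#' @param n_perm Subaverage permutations averaged per time point.
#' @param cost SVM regularisation constant.
#' @param standardize Z-score features using training-fold statistics.
#' @param seed RNG seed governing all subaverage assignments.
#' @return A `decoding_timecourse` tibble with columns `time` (ms) and
#'   `accuracy` (%); attributes record the configuration and the chance
#'   level (50).
#' @export
decode_timecourse <- function(epochs, labels = "physical", variant = NULL,
                              lookback = 20, stride = 1, n_subsets = 10,
                              n_perm = 100, cost = 1, standardize = TRUE,
                              seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  prep <- decode_prepare(epochs, labels, variant, lookback, stride, n_subsets)
  acc <- numeric(length(prep$t_idx))
  for (pr in seq_along(prep$pairs)) {
    pair <- prep$pairs[[pr]]
    acc <- acc + decode_engine(
      epochs$data, prep$idx[[pair[1]]], prep$idx[[pair[2]]], prep$t_idx,
      lookback, n_subsets, n_perm, cost, standardize,
      seed = child_seed(seed, 1000L + pr), tgm = FALSE
    )
  }
  acc <- acc / length(prep$pairs)
  out <- tibble::tibble(
    time = epochs$times[prep$t_idx],
    accuracy = 100 * acc
  )
  class(out) <- c("decoding_timecourse", class(out))
  attr(out, "chance") <- 50
  attr(out, "lookback") <- lookback
  attr(out, "n_perm") <- n_perm
  attr(out, "n_subsets") <- n_subsets
  attr(out, "classes") <- prep$classes
  out
}

#' Temporal generalization matrix
#'
#' Trains the sliding-window classifier at every decoded time point and
#' tests it at all decoded time points, reusing the cross-validation folds
#' of each subaverage permutation across testing times. The diagonal equals
#' the 1-d decoding time course exactly when both are run with the same
#' seed and configuration.
#'
#' @inheritParams decode_timecourse
#' @return A `tgm` object: list with `accuracy` (train x test matrix, %),
#'   `times` (ms), and the configuration attributes of
#'   [decode_timecourse()].
#' @export
temporal_generalization <- function(epochs, labels = "physical",
                                    variant = NULL, lookback = 20,
                                    stride = 1, n_subsets = 10, n_perm = 100,
                                    cost = 1, standardize = TRUE, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  prep <- decode_prepare(epochs, labels, variant, lookback, stride, n_subsets)
  nt <- length(prep$t_idx)
  acc <- matrix(0, nt, nt)
  for (pr in seq_along(prep$pairs)) {
    pair <- prep$pairs[[pr]]
    acc <- acc + decode_engine(
      epochs$data, prep$idx[[pair[1]]], prep$idx[[pair[2]]], prep$t_idx,
      lookback, n_subsets, n_perm, cost, standardize,
      seed = child_seed(seed, 1000L + pr), tgm = TRUE
    )
  }
  acc <- 100 * acc / length(prep$pairs)
  times <- epochs$times[prep$t_idx]
  dimnames(acc) <- list(train = times, test = times)
  structure(
    list(accuracy = acc, times = times, chance = 50, lookback = lookback,
         n_perm = n_perm, n_subsets = n_subsets, classes = prep$classes),
    class = "tgm"
  )
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf(
    "<decoding_timecourse> %d time points (%.0f..%.0f ms), mean %.1f%%\n",
    nrow(x), min(x$time), max(x$time), mean(x$accuracy)
  ))
  invisible(x)
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf(
    "<tgm> %d x %d (%.0f..%.0f ms), mean %.1f%%, diag peak %.1f%%\n",
    nrow(x$accuracy), ncol(x$accuracy), min(x$times), max(x$times),
    mean(x$accuracy), max(diag(x$accuracy))
  ))
  invisible(x)
}
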