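#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster permutation result
#'
#' @param x A `cluster_result` from [cluster_permutation_1d()] or
#'   [cluster_permutation_2d()].
#' @param ... Unused.
#' @return The clusters tibble (one row per cluster).
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname tidy.cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    threshold = x$threshold,
    alpha_cluster = x$alpha,
    n_perm = x$n_perm,
    statistic = x$statistic
  )
}

#' Tidy decoding results
#'
#' @param x A `decoding_timecourse` or `tgm`.
#' @param ... Unused.
#' @return A tibble: `time`/`accuracy` for time courses; `train_time`,
#'   `test_time`, `accuracy` (long form) for temporal generalization
#'   matrices.
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble::tibble(time = x$time, accuracy = x$accuracy)
}

#' @rdname tidy.decoding_timecourse
#' @export
glance.decoding_timecourse <- function(x, ...) {
  tibble::tibble(
    n_times = nrow(x), mean_accuracy = mean(x$accuracy),
    peak_accuracy = max(x$accuracy), peak_time = x$time[which.max(x$accuracy)],
    chance = attr(x, "chance")
  )
}

#' @rdname tidy.decoding_timecourse
#' @export
tidy.tgm <- function(x, ...) {
  grid <- expand.grid(train_time = x$times, test_time = x$times)
  tibble::tibble(
    train_time = grid$train_time, test_time = grid$test_time,
    accuracy = as.vector(x$accuracy)
  )
}

#' @rdname tidy.decoding_timecourse
#' @export
glance.tgm <- function(x, ...) {
  tibble::tibble(
    n_times = length(x$times), mean_accuracy = mean(x$accuracy),
    diag_peak = max(diag(x$accuracy)), chance = x$chance
  )
}

#' Plot a decoding time course
#'
#' @param object A `decoding_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = attr(object, "chance"),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = c(0, 2000), linetype = "dotted",
                        color = "grey70") +
    ggplot2::geom_line(color = "black") +
    ggplot2::labs(x = "time (ms)", y = "decoding accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot a temporal generalization matrix
#'
#' @param object A `tgm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tgm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test_time, y = .data$train_time,
                               fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = object$chance,
                                  low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "testing time (ms)", y = "training time (ms)",
                  fill = "accuracy (%)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a sensor layout
#'
#' @param object A `sensor_layout` tibble.
#' @param highlight Optional channel subset drawn in color.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensor_layout <- function(object, highlight = NULL, ...) {
  object$highlight <- object$channel %in% (highlight %||% character())
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$highlight), size = 2,
                        show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2.5,
                       vjust = -1) +
    ggplot2::scale_color_manual(values = c("grey40", "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL
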