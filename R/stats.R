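# t statistics against a constant for a subjects x points matrix under
# sign-flip permutations. `signs` is n_perm x n_subjects (+/-1); returns an
# n_perm x points matrix of t values. Uses the identity that flipping signs
# of (x - chance) leaves sum((x - chance)^2) unchanged.
signflip_tstats <- function(Xc, signs) {
  n <- nrow(Xc)
  ss <- colSums(Xc^2)
  m <- signs %*% Xc / n
  varm <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
  # ties across subjects (quantised accuracies) give zero variance; clamp so
  # a tied value exactly at chance maps to t = 0 and a tied value away from
  # chance to a large finite t, both handled consistently under sign flips
  varm[varm < 1e-24] <- 1e-24
  m / sqrt(varm / n)
}

# maximal contiguous suprathreshold runs of a logical vector as a tibble
runs_1d <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(start = starts[keep], end = ends[keep],
                 size = r$lengths[keep])
}

new_cluster_result <- function(clusters, threshold, alpha, n_perm, tail,
                               stat, null_max, statistic = "size") {
  structure(
    list(clusters = clusters, threshold = threshold, alpha = alpha,
         n_perm = n_perm, tail = tail, stat = stat, null_max = null_max,
         statistic = statistic),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), cluster-forming t > %.3f, %d permutations\n",
    nrow(x$clusters), x$threshold, x$n_perm
  ))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Cluster-size permutation test on subject curves
#'
#' Group-level inference for decoding time courses: a pointwise one-sample
#' t test against the chance level, a right-tailed cluster-forming threshold
#' at `alpha_cluster`, cluster statistic = cluster size (number of
#' contiguous suprathreshold points), and a Monte Carlo null distribution of
#' the maximal cluster size over random sign flips of the subject-wise
#' deviations from chance. Cluster p values use the (b + 1) / (m + 1)
#' convention.
#'
#' @param subject_curves Subjects x time matrix of accuracies (%), or a long
#'   tibble with `subject`, `time`, `accuracy` columns.
#' @param chance Chance level to test against (same units as the curves).
#' @param alpha_cluster Cluster-forming alpha (right tail).
#' @param n_perm Number of sign-flip permutations.
#' @param alpha Significance level applied to the cluster p values.
#' @param statistic Cluster statistic: `"size"` (count of points) or
#'   `"mass"` (sum of suprathreshold t values).
#' @param seed RNG seed.
#' @return A `cluster_result`: `clusters` tibble (`start`, `end` indices,
#'   `size`, `mass`, `p`, `significant`), the cluster-forming `threshold`,
#'   the pointwise t curve (`stat`), and the permutation null of the maximal
#'   cluster statistic (`null_max`).
#' @export
cluster_permutation_1d <- function(subject_curves, chance = 50,
                                   alpha_cluster = 0.05, n_perm = 1000,
                                   alpha = 0.05, statistic = c("size", "mass"),
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  X <- as_subject_matrix(subject_curves)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 subjects")
  Xc <- X - chance
  if (all(apply(Xc, 2, sd) < 1e-12)) {
    abort("degenerate input: zero variance across subjects at every point")
  }
  thr <- qt(1 - alpha_cluster, df = n - 1)
  tobs <- drop(signflip_tstats(Xc, matrix(1, 1, n)))
  cl <- runs_1d(tobs > thr)
  cl$mass <- vapply(seq_len(nrow(cl)), function(i) {
    sum(tobs[cl$start[i]:cl$end[i]])
  }, numeric(1))

  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  Tperm <- signflip_tstats(Xc, signs)
  null_max <- vapply(seq_len(n_perm), function(p) {
    r <- runs_1d(Tperm[p, ] > thr)
    if (!nrow(r)) return(0)
    if (statistic == "size") {
      max(r$size)
    } else {
      max(vapply(seq_len(nrow(r)), function(i) {
        sum(Tperm[p, r$start[i]:r$end[i]])
      }, numeric(1)))
    }
  }, numeric(1))

  obs_stat <- if (statistic == "size") cl$size else cl$mass
  cl$p <- vapply(obs_stat, function(s) {
    (sum(null_max >= s) + 1) / (n_perm + 1)
  }, numeric(1))
  cl$significant <- cl$p <= alpha
  new_cluster_result(cl, thr, alpha_cluster, n_perm, "right", tobs, null_max,
                     statistic)
}

as_subject_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    wide <- tidyr::pivot_wider(
      dplyr::arrange(x, .data$subject, .data$time),
      id_cols = "subject", names_from = "time", values_from = "accuracy"
    )
    return(as.matrix(wide[, -1, drop = FALSE]))
  }
  abort("expected a subjects x time matrix or a subject/time/accuracy tibble")
}

#' Cluster-size permutation test on subject matrices
#'
#' Two-dimensional analogue of [cluster_permutation_1d()] for temporal
#' generalization matrices: suprathreshold cells are grouped into
#' 4-connected components and the maximal component size (or mass) forms the
#' sign-flip permutation null.
#'
#' @param subject_matrices List of equally sized subject matrices (e.g. TGM
#'   accuracies in %), or a 3-d array subjects x rows x cols.
#' @inheritParams cluster_permutation_1d
#' @return A `cluster_result` whose `clusters` tibble has one row per
#'   observed component (`id`, `size`, `mass`, `p`, `significant`) and whose
#'   `stat` is the observed t matrix; `labels` holds the component map.
#' @export
cluster_permutation_2d <- function(subject_matrices, chance = 50,
                                   alpha_cluster = 0.05, n_perm = 1000,
                                   alpha = 0.05, statistic = c("size", "mass"),
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  if (is.list(subject_matrices)) {
    dims <- dim(subject_matrices[[1]])
    A <- array(0, dim = c(length(subject_matrices), dims))
    for (i in seq_along(subject_matrices)) A[i, , ] <- subject_matrices[[i]]
  } else {
    A <- subject_matrices
    dims <- dim(A)[2:3]
  }
  n <- dim(A)[1]
  if (n < 2) abort("need at least 2 subjects")
  X <- A
  dim(X) <- c(n, prod(dims))
  Xc <- X - chance
  if (all(apply(Xc, 2, sd) < 1e-12)) {
    abort("degenerate input: zero variance across subjects at every cell")
  }
  thr <- qt(1 - alpha_cluster, df = n - 1)
  tobs <- matrix(drop(signflip_tstats(Xc, matrix(1, 1, n))), dims[1], dims[2])
  lab <- .cpp_label_2d(tobs > thr)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cl <- tibble::tibble(
    id = ids,
    size = vapply(ids, function(i) sum(lab == i), numeric(1)),
    mass = vapply(ids, function(i) sum(tobs[lab == i]), numeric(1))
  )

  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  Tperm <- signflip_tstats(Xc, signs)
  null_max <- vapply(seq_len(n_perm), function(p) {
    m <- matrix(Tperm[p, ], dims[1], dims[2]) > thr
    if (statistic == "size") {
      as.numeric(.cpp_max_cluster_2d(m))
    } else {
      lb <- .cpp_label_2d(m)
      if (!any(lb > 0)) return(0)
      tm <- matrix(Tperm[p, ], dims[1], dims[2])
      max(vapply(setdiff(unique(as.vector(lb)), 0L),
                 function(i) sum(tm[lb == i]), numeric(1)))
    }
  }, numeric(1))

  obs_stat <- if (statistic == "size") cl$size else cl$mass
  cl$p <- vapply(obs_stat, function(s) {
    (sum(null_max >= s) + 1) / (n_perm + 1)
  }, numeric(1))
  cl$significant <- cl$p <= alpha
  out <- new_cluster_result(cl, thr, alpha_cluster, n_perm, "right", tobs,
                            null_max, statistic)
  out$labels <- lab
  out
}

#' Brain-behavior correlation time course
#'
#' Relates condition-specific neural decodability to behavior: for each
#' subject and time point, the Spearman rank correlation across fake
#' variants between the subject's per-variant behavioral accuracy and the
#' per-variant (real vs that variant) decoding accuracy. Group inference on
#' the correlation curves uses the 1-d cluster-size permutation test against
#' zero.
#'
#' @param decoding Long tibble with columns `subject`, `variant`, `time`,
#'   `accuracy` (decoding accuracy, %).
#' @param behavior Tibble with columns `subject`, `variant`, `accuracy`
#'   (behavioral proportion correct).
#' @param n_perm,alpha_cluster,alpha,seed Passed to
#'   [cluster_permutation_1d()] (against chance 0).
#' @return A `correlation_timecourse`: tibble `subject`, `time`, `rho`, with
#'   attributes `group` (tibble `time`, `mean_rho`) and `inference` (the
#'   [cluster_permutation_1d()] result on the rho curves).
#' @export
brain_behavior_correlation <- function(decoding, behavior, n_perm = 1000,
                                       alpha_cluster = 0.05, alpha = 0.05,
                                       seed = 1L) {
  nv <- length(unique(decoding$variant))
  if (nv < 3) abort("rank correlation needs >= 3 variants")
  merged <- dplyr::inner_join(
    decoding,
    dplyr::rename(behavior, behav = "accuracy"),
    by = c("subject", "variant")
  )
  rho <- merged |>
    dplyr::group_by(.data$subject, .data$time) |>
    dplyr::summarise(
      rho = cor(.data$accuracy, .data$behav, method = "spearman"),
      .groups = "drop"
    )
  group <- rho |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean_rho = mean(.data$rho), .groups = "drop")
  wide <- as_subject_matrix(dplyr::rename(rho, accuracy = "rho"))
  # perfectly aligned inputs give rho = 1 everywhere, which leaves nothing
  # for a sign-flip test to resample; report the curves without inference
  inference <- tryCatch(
    cluster_permutation_1d(
      wide, chance = 0, alpha_cluster = alpha_cluster, n_perm = n_perm,
      alpha = alpha, seed = seed
    ),
    error = function(e) NULL
  )
  structure(rho, class = c("correlation_timecourse", class(rho)),
            group = group, inference = inference,
            times = sort(unique(rho$time)))
}

#' Wilcoxon signed-rank test with effect size
#'
#' One-sample (or paired) signed-rank test: ranks of the absolute nonzero
#' differences, normal-approximation Z with tie correction, exact p value
#' from the signed-rank null distribution when there are no ties and n <= 50
#' (normal approximation otherwise), and the rank-biserial-style effect size
#' r = Z / sqrt(N).
#'
#' @param x Per-subject values (e.g. accuracies).
#' @param y Paired comparison values, or a scalar chance level.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return A tibble with `n`, `V` (signed-rank statistic), `Z`, `p`,
#'   `effect_r`.
#' @export
behavior_tests <- function(x, y = 0.5, alternative = c("two.sided", "greater",
                                                       "less")) {
  alternative <- match.arg(alternative)
  if (length(y) == 1L) y <- rep(y, length(x))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) abort("all differences are zero (all-tied input)")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  Z <- (V - mu) / sqrt(sig2)
  exact <- !any(duplicated(abs(d))) && n <= 50
  p <- if (exact) {
    switch(alternative,
      two.sided = {
        pl <- stats::psignrank(V, n)
        pu <- 1 - stats::psignrank(V - 1, n)
        min(1, 2 * min(pl, pu))
      },
      greater = 1 - stats::psignrank(V - 1, n),
      less = stats::psignrank(V, n)
    )
  } else {
    switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(Z)),
      greater = stats::pnorm(Z, lower.tail = FALSE),
      less = stats::pnorm(Z)
    )
  }
  tibble::tibble(n = n, V = V, Z = Z, p = p, effect_r = Z / sqrt(n))
}
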