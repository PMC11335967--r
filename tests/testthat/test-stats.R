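test_that("a strong uniform effect yields one epoch-spanning cluster at minimal p", {
  X <- withr::with_seed(1, matrix(rnorm(20 * 50, mean = 60, sd = 2), 20, 50))
  res <- cluster_permutation_1d(X, chance = 50, n_perm = 199, seed = 2)
  cl <- tidy(res)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 1)
  expect_equal(cl$end, 50)
  expect_true(cl$significant)
  # the size statistic saturates at the epoch length, so strongly imbalanced
  # sign flips can tie it; the mass statistic breaks those ties and attains
  # the minimal attainable Monte Carlo p of 1 / (n_perm + 1)
  resm <- cluster_permutation_1d(X, chance = 50, n_perm = 199, seed = 2,
                                 statistic = "mass")
  expect_equal(tidy(resm)$p, 1 / 200)
})

test_that("cluster extents equal a brute-force recomputation from the t curve", {
  withr::with_seed(5, {
    X <- matrix(rnorm(12 * 80, mean = 50), 12, 80)
    X[, 20:30] <- X[, 20:30] + 1.5
    X[, 60:64] <- X[, 60:64] + 1.2
    res <- cluster_permutation_1d(X, chance = 50, n_perm = 99, seed = 1)
    # independent oracle: pointwise t tests + manual run detection
    tvals <- apply(X, 2, function(v) t.test(v, mu = 50)$statistic)
    thr <- qt(0.95, df = 11)
    above <- tvals > thr
    expect_equal(res$stat, unname(tvals), tolerance = 1e-10)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    expect_equal(tidy(res)$start, starts[runs$values])
    expect_equal(tidy(res)$end, ends[runs$values])
    expect_equal(tidy(res)$size, runs$lengths[runs$values])
  })
})

test_that("cluster inference is deterministic in seed and invariant to subject order", {
  X <- withr::with_seed(9, matrix(rnorm(10 * 40, mean = 50.7), 10, 40))
  a <- cluster_permutation_1d(X, n_perm = 99, seed = 4)
  b <- cluster_permutation_1d(X, n_perm = 99, seed = 4)
  expect_identical(tidy(a), tidy(b))
  # permuting subjects leaves the observed clusters unchanged
  c <- cluster_permutation_1d(X[sample(10), ], n_perm = 99, seed = 4)
  expect_equal(tidy(a)$size, tidy(c)$size)
})

test_that("lowering the cluster-forming alpha never adds suprathreshold points", {
  X <- withr::with_seed(2, matrix(rnorm(14 * 60, mean = 50.4), 14, 60))
  n_above <- vapply(c(0.10, 0.05, 0.01), function(a) {
    res <- cluster_permutation_1d(X, alpha_cluster = a, n_perm = 49, seed = 1)
    sum(tidy(res)$size)
  }, numeric(1))
  expect_true(all(diff(n_above) <= 0))
})

test_that("degenerate zero-variance curves abort", {
  X <- matrix(50, 5, 20)
  expect_error(cluster_permutation_1d(X), "degenerate")
})

test_that("2-d cluster inference finds block effects with 4-connectivity", {
  withr::with_seed(3, {
    n <- 16
    mats <- lapply(1:n, function(i) {
      m <- matrix(rnorm(30 * 30, mean = 50), 30, 30)
      m[10:18, 12:20] <- m[10:18, 12:20] + 4
      m
    })
    res <- cluster_permutation_2d(mats, chance = 50, n_perm = 99, seed = 1)
    cl <- tidy(res)
    big <- cl[which.max(cl$size), ]
    expect_true(big$significant)
    # the significant component covers the injected block
    lab <- res$labels
    expect_true(all(lab[10:18, 12:20] == big$id))
  })

  # a single suprathreshold cell forms a cluster of size 1
  withr::with_seed(8, {
    mats <- lapply(1:10, function(i) matrix(rnorm(6 * 6, 50), 6, 6))
    mats <- lapply(mats, function(m) { m[3, 3] <- m[3, 3] + 6; m })
    res <- cluster_permutation_2d(mats, chance = 50, n_perm = 49, seed = 2)
    expect_true(1 %in% tidy(res)$size)
  })
})

test_that("connected-component labelling matches a reference flood fill", {
  withr::with_seed(11, {
    mask <- matrix(runif(15 * 12) < 0.4, 15, 12)
    lab <- reverbdecode:::.cpp_label_2d(mask)
    expect_equal(lab > 0, mask)
    # any two 4-adjacent TRUE cells share a label
    for (r in 1:14) for (c in 1:12) {
      if (mask[r, c] && mask[r + 1, c]) expect_equal(lab[r, c], lab[r + 1, c])
    }
    for (r in 1:15) for (c in 1:11) {
      if (mask[r, c] && mask[r, c + 1]) expect_equal(lab[r, c], lab[r, c + 1])
    }
    # labels are 1..n_components and the max component size is consistent
    expect_equal(max(lab), length(unique(lab[lab > 0])))
    expect_equal(reverbdecode:::.cpp_max_cluster_2d(mask), max(table(lab[lab > 0])))
  })
})

test_that("brain-behavior correlation recovers perfect rank alignments", {
  dec <- tidyr::expand_grid(subject = 1:6, variant = letters[1:5],
                            time = c(0, 10))
  dec$accuracy <- 10 * as.integer(factor(dec$variant))
  beh <- tidyr::expand_grid(subject = 1:6, variant = letters[1:5])
  beh$accuracy <- rep(seq(0.5, 0.9, by = 0.1), times = 6)
  res <- brain_behavior_correlation(dec, beh, n_perm = 19, seed = 1)
  expect_equal(res$rho, rep(1, nrow(res)))

  beh$accuracy <- rep(seq(0.9, 0.5, by = -0.1), times = 6)
  res2 <- brain_behavior_correlation(dec, beh, n_perm = 19, seed = 1)
  expect_equal(res2$rho, rep(-1, nrow(res2)))

  expect_error(
    brain_behavior_correlation(dplyr::filter(dec, variant %in% c("a", "b")),
                               beh, n_perm = 19),
    ">= 3 variants"
  )
})

test_that("independent decoding and behavior give near-zero group correlation", {
  withr::with_seed(4, {
    dec <- tidyr::expand_grid(subject = 1:10, variant = letters[1:5],
                              time = seq(0, 90, by = 10))
    dec$accuracy <- rnorm(nrow(dec), 50, 5)
    beh <- tidyr::expand_grid(subject = 1:10, variant = letters[1:5])
    beh$accuracy <- runif(nrow(beh), 0.4, 1)
    res <- brain_behavior_correlation(dec, beh, n_perm = 99, seed = 2)
    grp <- attr(res, "group")
    expect_lt(max(abs(grp$mean_rho)), 0.5)
    expect_equal(sum(tidy(attr(res, "inference"))$significant), 0)
  })
})

test_that("signed-rank behavior tests match the exact null distribution", {
  # uniform positive shift: all 20 subjects at 60% vs 50% chance
  res <- behavior_tests(rep(0.60, 20), 0.5, alternative = "greater")
  expect_gt(res$Z, 0)
  expect_lt(res$p, 0.001)

  # symmetric values around chance: p near 1
  x <- 0.5 + c(-0.04, 0.04, -0.03, 0.03, -0.02, 0.02, -0.01, 0.01)
  expect_gt(behavior_tests(x, 0.5)$p, 0.5)

  # exact (V, p) against a brute-force enumeration oracle at n = 12
  withr::with_seed(6, {
    d <- rnorm(12)
    res <- behavior_tests(d, 0)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    expect_equal(res$V, V)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
    Vnull <- signs %*% r
    p_exact <- min(1, 2 * min(mean(Vnull >= V), mean(Vnull <= V)))
    expect_equal(res$p, p_exact, tolerance = 1e-10)
  })

  expect_error(behavior_tests(rep(0.5, 8), 0.5), "tied")
})
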