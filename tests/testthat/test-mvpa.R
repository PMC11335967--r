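test_that("window stacking has the documented dimensionality and ordering", {
  ep <- noise_epochs(4, 5, 30)
  X <- stack_window(ep, 25, lookback = 2)
  expect_equal(dim(X), c(4, 15))
  # channel-major by time: first block = all channels at t - lookback
  expect_equal(X[3, 1:5], ep$data[3, , 23], ignore_attr = TRUE)
  expect_equal(X[3, 11:15], ep$data[3, , 25], ignore_attr = TRUE)

  expect_equal(ncol(stack_window(ep, 10, lookback = 0)), 5)
  expect_error(stack_window(ep, 2, lookback = 2), "t_index")
})

test_that("subaveraging forms near-equal pseudo-trials preserving the mean", {
  X <- matrix(withr::with_seed(1, rnorm(50 * 7)), 50, 7)
  P <- make_subaverages(X, 10, seed = 3)
  expect_equal(dim(P), c(10, 7))
  expect_equal(colMeans(P), colMeans(X), tolerance = 1e-12)
  expect_error(make_subaverages(X[1:9, ], 10), "at least 10")
})

test_that("the SMO linear SVM agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- 18; d <- 40
      X <- matrix(rnorm(n * d), n)
      X[1:(n / 2), 1:3] <- X[1:(n / 2), 1:3] + rnorm(1)
      y <- rep(c(1, -1), each = n / 2)
      mine <- reverbdecode:::.cpp_svm_fit(X, y, 1)
      ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                        cost = 1, scale = FALSE)
      w_ref <- as.vector(t(ref$coefs) %*% ref$SV)
      b_ref <- -ref$rho
      Xt <- matrix(rnorm(20 * d), 20)
      f_mine <- as.vector(Xt %*% mine$w) + mine$b
      f_ref <- as.vector(Xt %*% w_ref) + b_ref
      # decision values agree to solver tolerance; predictions coincide
      expect_lt(max(abs(f_mine - f_ref)), 5e-3)
      expect_identical(sign(f_mine[abs(f_ref) > 0.01]),
                       sign(f_ref[abs(f_ref) > 0.01]))
    }
  })
})

test_that("decoding separable classes reaches 100% at informative samples", {
  ep <- separable_epochs(20, 6, 40, gap = 8)
  tc <- decode_timecourse(ep, "physical", lookback = 2, stride = 4,
                          n_subsets = 5, n_perm = 3, seed = 1)
  expect_true(all(tc$accuracy > 95))
  expect_true(all(tc$accuracy <= 100))
})

test_that("the decoding time course starts at epoch start + lookback", {
  ep <- noise_epochs(12, 4, 290, sfreq = 100, t0 = -400)
  tc <- decode_timecourse(ep, "physical", lookback = 20, stride = 50,
                          n_subsets = 5, n_perm = 2, seed = 1)
  expect_equal(tc$time[1], -200)
})

test_that("accuracy is invariant to channel-wise affine rescaling when standardizing", {
  ep <- separable_epochs(16, 5, 30, gap = 2, seed = 5)
  sc <- ep
  for (ch in 1:5) sc$data[, ch, ] <- sc$data[, ch, ] * (ch * 3) + ch
  a <- decode_timecourse(ep, "physical", lookback = 2, stride = 6,
                         n_subsets = 4, n_perm = 3, seed = 7)
  b <- decode_timecourse(sc, "physical", lookback = 2, stride = 6,
                         n_subsets = 4, n_perm = 3, seed = 7)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-9)
})

test_that("temporal generalization reuses folds so its diagonal is the 1-d curve", {
  ep <- separable_epochs(16, 5, 36, gap = 2, seed = 8)
  tc <- decode_timecourse(ep, "physical", lookback = 3, stride = 3,
                          n_subsets = 4, n_perm = 4, seed = 11)
  tg <- temporal_generalization(ep, "physical", lookback = 3, stride = 3,
                                n_subsets = 4, n_perm = 4, seed = 11)
  expect_equal(diag(tg$accuracy), tc$accuracy, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tg$times, tc$time)
})

test_that("an effect confined to one window generalizes only within it", {
  withr::with_seed(13, {
    n_tr <- 24; n_ch <- 6; n_t <- 40
    dat <- array(rnorm(n_tr * n_ch * n_t), c(n_tr, n_ch, n_t))
    real <- rep(c(TRUE, FALSE), each = n_tr / 2)
    win <- 25:32
    dat[real, 1:3, win] <- dat[real, 1:3, win] + 4
    ep <- epoch_set(dat, seq(0, by = 10, length.out = n_t),
                    sprintf("c%d", 1:n_ch), 100,
                    tibble::tibble(class = ifelse(real, "real", "fake")))
    tg <- temporal_generalization(ep, "physical", lookback = 2, stride = 2,
                                  n_subsets = 6, n_perm = 3, seed = 3)
    inw <- tg$times >= 270 & tg$times <= 320
    out <- tg$times <= 150
    expect_gt(mean(tg$accuracy[inw, inw]), 90)
    expect_lt(mean(tg$accuracy[out, out]), 65)
    expect_lt(mean(tg$accuracy[inw, out]), 65)
  })
})

test_that("multiclass control labelings decode via averaged pairwise accuracy", {
  withr::with_seed(21, {
    dat <- array(rnorm(24 * 4 * 20), c(24, 4, 20))
    loc <- rep(1:4, each = 6)
    dat[, 1, ] <- dat[, 1, ] + 5 * loc # separable 4-class signal
    ep <- epoch_set(dat, seq(0, by = 10, length.out = 20),
                    sprintf("c%d", 1:4), 100,
                    tibble::tibble(class = rep(c("real", "fake"), 12),
                                   response_location = loc))
    tc <- decode_timecourse(ep, "response_location", lookback = 1, stride = 5,
                            n_subsets = 4, n_perm = 2, seed = 2)
    expect_gt(mean(tc$accuracy), 90)
    expect_equal(length(attr(tc, "classes")), 4)
  })
})

test_that("sensor clusters around the canonical centroids match the montage", {
  lay <- sensor_layout_1020()
  cl <- preset_sensor_clusters(lay)
  expect_setequal(cl$temporal,
                  c("FC5", "FC6", "FT9", "FT10", "C3", "C4", "CP5", "CP6",
                    "T7", "T8", "TP9", "TP10"))
  expect_setequal(cl$centroparietal, c("Cz", "Pz", "P3", "P4", "CP1", "CP2"))

  expect_setequal(select_sensor_cluster(lay, c("T7", "T8"), 0), c("T7", "T8"))
  expect_error(select_sensor_cluster(lay, "XX9", 0.5), "unknown centroid")
})

test_that("insufficient per-class trials abort decoding", {
  ep <- noise_epochs(10, 3, 30)
  expect_error(decode_timecourse(ep, "physical", n_subsets = 10), "n_subsets")
})
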