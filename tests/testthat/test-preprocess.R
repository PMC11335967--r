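test_that("common-average re-referencing zeroes the channel mean and is idempotent", {
  ep <- noise_epochs(6, 5, 40)
  re <- rereference_common_average(ep)
  expect_equal(max(abs(apply(re$data, c(1, 3), mean))), 0, tolerance = 1e-12)
  re2 <- rereference_common_average(re)
  expect_equal(re2$data, re$data, tolerance = 1e-12)

  # two channels (a, b) -> ((a-b)/2, (b-a)/2)
  two <- subset_epochs(ep, channels = 1:2)
  r2 <- rereference_common_average(two)
  expect_equal(r2$data[, 1, ], (two$data[, 1, ] - two$data[, 2, ]) / 2,
               tolerance = 1e-12)
  expect_equal(r2$data[, 2, ], -r2$data[, 1, ], tolerance = 1e-12)

  expect_error(rereference_common_average(subset_epochs(ep, channels = 1)),
               ">= 2 channels")
})

test_that("baseline correction zeroes the window mean and ignores offsets", {
  ep <- noise_epochs(6, 5, 60, sfreq = 100, t0 = -400)
  bc <- baseline_correct(ep, c(-200, 0))
  sel <- bc$times >= -200 & bc$times <= 0
  expect_equal(max(abs(apply(bc$data[, , sel], c(1, 2), mean))), 0,
               tolerance = 1e-12)

  shifted <- ep
  shifted$data <- ep$data + rep(1:5, each = 6) # per-channel constants
  expect_equal(baseline_correct(shifted, c(-200, 0))$data, bc$data,
               tolerance = 1e-12)

  whole <- baseline_correct(ep, range(ep$times))
  expect_equal(max(abs(apply(whole$data, c(1, 2), mean))), 0, tolerance = 1e-12)

  expect_error(baseline_correct(ep, c(5000, 6000)), "outside")
})

test_that("boxcar downsampling averages nonoverlapping bins", {
  des <- simulation_design(4, seed = 1)
  ep <- simulate_eeg_epochs(des, layout = sensor_layout_1020()[1:4, ],
                            seed = 1)
  dn <- downsample_boxcar(ep, 10)
  expect_equal(dim(dn$data)[3], 290)
  expect_equal(dn$sfreq, 100)
  expect_equal(dn$times[1:3], c(-400, -390, -380))
  expect_equal(dn$data[2, 3, 7], mean(ep$data[2, 3, 61:70]),
               tolerance = 1e-12, ignore_attr = TRUE)

  const <- noise_epochs(2, 2, 40)
  const$data[] <- 3.5
  expect_true(all(downsample_boxcar(const, 20)$data == 3.5))

  expect_error(downsample_boxcar(noise_epochs(2, 2, 45), 20), "divide")
})

test_that("the low-pass filter is zero-phase with the expected frequency response", {
  sfreq <- 100
  n <- 300
  tt <- (0:(n - 1)) / sfreq
  mk <- function(f) {
    dat <- array(0, c(1, 2, n))
    dat[1, 1, ] <- sin(2 * pi * f * tt)
    dat[1, 2, ] <- rnorm(n, sd = 0.01)
    epoch_set(dat, tt * 1000, c("a", "b"), sfreq)
  }
  pass <- lowpass_epochs(mk(5), 30)
  mid <- 100:200
  expect_equal(max(abs(pass$data[1, 1, mid])), 1, tolerance = 0.05)

  # 4th-order Butterworth applied twice: |H(45 Hz)|^2 ~ 0.04 at 30 Hz cutoff
  stopb <- lowpass_epochs(mk(45), 30)
  expect_lt(max(abs(stopb$data[1, 1, mid])), 0.1)

  # zero-phase: a symmetric pulse stays symmetric around its peak
  dat <- array(0, c(1, 1, n))
  dat[1, 1, ] <- exp(-((tt - 1.5)^2) / (2 * 0.05^2))
  ep <- epoch_set(dat, tt * 1000, "a", sfreq)
  sm <- lowpass_epochs(ep, 10)$data[1, 1, ]
  pk <- which.max(sm)
  k <- 1:60
  expect_equal(sm[pk - k], sm[pk + k], tolerance = 1e-6)

  expect_error(lowpass_epochs(mk(5), 60), "Nyquist")
})

test_that("label schemes partition trials as specified", {
  des <- simulation_design(40, seed = 2)
  des <- simulate_behavior(des, seed = 3)
  ep <- noise_epochs(40, 4, 30)
  ep$labels <- des

  phys <- label_trials(ep, "physical")
  expect_equal(unname(c(attr(phys, "counts"))), c(20, 20))

  perc <- label_trials(ep, "perceived")
  expect_identical(as.character(perc$class),
                   ifelse(des$correct, as.character(des$class),
                          ifelse(des$class == "real", "fake", "real")))

  vr <- label_trials(ep, "variant_vs_real", variant = "ecological")
  expect_setequal(as.character(vr$class), c("real", "fake"))
  expect_true(all(des$variant[vr$trial] %in% c("real_like", "ecological")))
  expect_error(label_trials(ep, "variant_vs_real"), "variant")

  corr <- label_trials(ep, "correct_only")
  expect_identical(corr$trial, which(des$correct))

  bh <- label_trials(ep, "block_half")
  expect_setequal(levels(bh$class), c("first_half", "last_half"))

  ep$labels$room_id <- NULL
  expect_error(label_trials(ep, "room_id"), "lack column")
})
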