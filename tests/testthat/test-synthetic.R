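test_that("dry sources have the requested size and syllabic modulation", {
  fs <- 16e3
  src <- generate_dry_source(3, fs, "A", seed = 1)
  expect_length(src$waveform, 3 * fs)

  # modulation-spectrum oracle: broadband envelope via rectify + smooth,
  # then FFT; the peak must fall in the 2-8 Hz syllabic range
  env <- abs(src$waveform)
  env <- stats::filter(env, rep(1 / 800, 800), sides = 2)
  env <- env[!is.na(env)]
  env <- env - mean(env)
  n <- length(env)
  spec <- Mod(fft(env))[2:floor(n / 2)]
  freqs <- (2:floor(n / 2) - 1) / n * fs
  peak_f <- freqs[which.max(spec)]
  expect_gt(peak_f, 2)
  expect_lt(peak_f, 8)

  src2 <- generate_dry_source(3, fs, "A", seed = 2)
  expect_false(identical(src$waveform, src2$waveform))
  expect_equal(rms(src$waveform), rms(src2$waveform), tolerance = 1e-9)
})

test_that("speaker attributes differ in fundamental-frequency band", {
  fs <- 16e3
  f0_of <- function(attr, seed) {
    w <- generate_dry_source(2, fs, attr, seed = seed)$waveform
    spec <- Mod(fft(w))[1:(fs)]
    (which.max(spec[30:600]) + 28) / 2 # 2 s window: bin resolution 0.5 Hz
  }
  expect_lt(f0_of("A", 3), 150)
  expect_gt(f0_of("B", 3), 170)
})

test_that("simulated epochs have the right shape and honor effect windows", {
  lay <- sensor_layout_1020()
  des <- simulation_design(8, seed = 1)
  ep <- simulate_eeg_epochs(des, effects = list(), layout = lay, seed = 1)
  expect_equal(dim(ep$data), c(8, nrow(lay), 2900))
  expect_equal(ep$times[1], -400)
  expect_equal(ep$times[2900], 2499)

  bad <- effect_spec(c("Cz"), c(2400, 2600))
  expect_error(
    simulate_eeg_epochs(des, effects = list(bad), layout = lay, seed = 1),
    "outside the epoch"
  )

  # the class contrast concentrates in the effect window over its channels
  eff <- effect_spec(c("T7", "T8"), c(470, 960), amplitude = 20,
                     subject_sdlog = 0)
  ep2 <- simulate_eeg_epochs(des, effects = list(eff),
                             noise = noise_spec(pink_sd = 0, white_sd = 0.01),
                             layout = lay, seed = 2)
  fake <- ep2$labels$class == "fake"
  dif <- apply(ep2$data[fake, , , drop = FALSE], c(2, 3), mean) -
    apply(ep2$data[!fake, , , drop = FALSE], c(2, 3), mean)
  inw <- ep2$times >= 470 & ep2$times <= 960
  t7 <- match("T7", ep2$channels)
  cz <- match("Cz", ep2$channels)
  expect_gt(max(abs(dif[t7, inw])), 15)
  expect_lt(max(abs(dif[t7, !inw])), 1)
  expect_lt(max(abs(dif[cz, ])), 1)

  # determinism
  ep3 <- simulate_eeg_epochs(des, effects = list(eff),
                             noise = noise_spec(pink_sd = 0, white_sd = 0.01),
                             layout = lay, seed = 2)
  expect_identical(ep2$data, ep3$data)
})

test_that("behavioral simulation follows the per-variant probabilities", {
  des <- simulation_design(600, seed = 3)
  all_right <- simulate_behavior(
    des, p_correct = stats::setNames(rep(1, 6), names(default_p_correct())),
    seed = 1
  )
  expect_true(all(all_right$correct))
  expect_identical(all_right$perceived, as.character(all_right$class))

  # perceived = physical XOR (not correct), trialwise
  beh <- simulate_behavior(des, seed = 2)
  flipped <- beh$perceived != beh$class
  expect_identical(flipped, !beh$correct)

  # p = 0.5 lands inside the binomial 99% CI around 0.5
  half <- simulate_behavior(
    des, p_correct = stats::setNames(rep(0.5, 6), names(default_p_correct())),
    seed = 3
  )
  expect_lt(abs(mean(half$correct) - 0.5), 2.58 * sqrt(0.25 / 600))

  # empirical accuracy ordering matches the probability ordering at large n
  big <- simulate_behavior(simulation_design(3000, seed = 4), seed = 5)
  acc <- tapply(big$correct, big$variant, mean)
  p <- default_p_correct()
  key <- ifelse(names(acc) == "real_like", "real", names(acc))
  expect_equal(order(acc), order(p[key]))
})

test_that("default behavioral probabilities reproduce the headline accuracy", {
  p <- default_p_correct()
  expect_equal(mean(p[-1]), 0.6943, tolerance = 1e-3)
  expect_equal((p[["real"]] + mean(p[-1])) / 2, 0.757, tolerance = 1e-3)
})
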