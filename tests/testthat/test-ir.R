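test_that("broadband RT60 matches the closed form on noiseless exponentials", {
  fs <- 8000
  for (tau in c(0.1, 0.145, 0.3)) {
    ir <- impulse_response(exp(-(0:(3 * fs)) / fs / tau), fs)
    rt <- measure_rt60(ir)
    expect_true(attr(rt, "valid"))
    expect_equal(as.numeric(rt), 6.9078 * tau, tolerance = 0.02)
  }
})

test_that("non-decaying energy is flagged as an invalid fit", {
  fs <- 8000
  rising <- impulse_response(exp((0:(2 * fs)) / fs / 0.3) *
                               withr::with_seed(1, rnorm(2 * fs + 1)), fs)
  rt <- measure_rt60(rising)
  expect_false(attr(rt, "valid"))
  expect_true(is.na(rt))
})

test_that("synthesis is deterministic and measurable at the target RT60", {
  fb <- small_fb()
  prof <- decay_profile(rep(1.0, fb$n_bands))
  env <- transform_profile(prof, "ecological", 2, fb$sample_rate)
  ir_a <- synthesize_ir(env, fb, seed = 5)
  ir_b <- synthesize_ir(env, fb, seed = 5)
  expect_identical(ir_a$waveform, ir_b$waveform)
  expect_false(identical(ir_a$waveform, synthesize_ir(env, fb, seed = 6)$waveform))

  rt <- measure_rt60(ir_a)
  expect_true(attr(rt, "valid"))
  expect_equal(as.numeric(rt), 1.0, tolerance = 0.1)
})

test_that("time-reversed synthesis rises over time and fails the decay fit", {
  fb <- small_fb()
  prof <- decay_profile(rep(1.0, fb$n_bands))
  env <- transform_profile(prof, "time_reversed", 2, fb$sample_rate)
  ir <- synthesize_ir(env, fb, seed = 2)
  # broadband log-envelope slope is positive
  n <- length(ir$waveform)
  le <- 10 * log10(rev(cumsum(rev(ir$waveform^2))) + 1e-30)
  tt <- seq_len(n) / fb$sample_rate
  half <- seq(0.1 * n, 0.9 * n)
  sl <- coef(lm(10 * log10(ir$waveform[half]^2 + 1e-20) ~ tt[half]))[[2]]
  expect_gt(sl, 0)
  expect_false(attr(measure_rt60(ir), "valid"))
})

test_that("variant transforms reshape decay as specified", {
  fb <- small_fb()
  K <- fb$n_bands
  # monotonically decreasing RT60 with frequency, as in real rooms
  prof <- decay_profile(seq(1.6, 0.7, length.out = K))

  # flat_spectral: zero across-band RT60 variance by construction
  flat <- transform_profile(prof, "flat_spectral", 2, fb$sample_rate)
  rt_out <- apply(flat$env, 2, function(e) {
    tt <- seq_along(e) / fb$sample_rate
    -60 / coef(lm(20 * log10(e) ~ tt))[[2]]
  })
  expect_equal(var(rt_out), 0, tolerance = 1e-12)

  # ecological: exponential envelopes reproducing the profile exactly
  eco <- transform_profile(prof, "ecological", 2, fb$sample_rate)
  t <- (seq_len(nrow(eco$env)) - 1) / fb$sample_rate
  expect_equal(eco$env[, 3], 10^(-3 * t / prof$band_rt60[3]), tolerance = 1e-12)

  # inverted_spectral: minimum RT60 moves to a middle band
  inv <- transform_profile(prof, "inverted_spectral", 2, fb$sample_rate)
  rt_inv <- apply(inv$env, 2, function(e) {
    tt <- seq_along(e) / fb$sample_rate
    -60 / coef(lm(20 * log10(e) ~ tt))[[2]]
  })
  expect_true(which.min(rt_inv) > K / 4 && which.min(rt_inv) < 3 * K / 4)

  # linear_decay: amplitude linear in time, zero at the band's -60 dB point
  lin <- transform_profile(prof, "linear_decay", 2, fb$sample_rate)
  k <- 5
  zero_at <- t[which(lin$env[, k] == 0)[1]]
  expect_equal(zero_at, prof$band_rt60[k], tolerance = 1e-3)
  expect_equal(diff(lin$env[1:100, k]),
               rep(diff(lin$env[1:2, k]), 99), tolerance = 1e-9)

  expect_error(transform_profile(prof, "nonsense", 2, fb$sample_rate))
})

test_that("time reversal of envelope sets is an exact involution", {
  fb <- small_fb()
  prof <- decay_profile(seq(1.4, 0.6, length.out = fb$n_bands))
  eco <- transform_profile(prof, "ecological", 1, fb$sample_rate)
  twice <- reverse_envelopes(reverse_envelopes(eco))
  expect_identical(twice$env, eco$env)
  expect_identical(twice$shape_kind, eco$shape_kind)
  rev1 <- transform_profile(prof, "time_reversed", 1, fb$sample_rate)
  expect_identical(reverse_envelopes(eco)$env, rev1$env)
})

test_that("generate-then-estimate recovers subband decay profiles", {
  fb <- small_fb()
  K <- fb$n_bands

  # flat profile: every band within 10% (averaged over a few noise seeds)
  prof <- decay_profile(rep(1.0, K))
  est <- sapply(1:3, function(s) {
    ir <- synthesize_ir(transform_profile(prof, "ecological", 3, fb$sample_rate),
                        fb, seed = s)
    estimate_decay_profile(ir, fb)$band_rt60
  })
  expect_true(all(abs(rowMeans(est) - 1.0) < 0.1))

  # smooth profiles spanning [0.5, 2]: mean band error < 10 %, worst < 20 %
  # (heavily non-smooth profiles are limited by subband overlap leakage)
  for (case in 1:2) {
    sm <- withr::with_seed(case, {
      ph <- runif(1, 0, 2 * pi)
      1.25 + 0.75 * sin(ph + 2 * pi * (1:K) / K)
    })
    prof <- decay_profile(sm)
    est <- sapply(1:3, function(s) {
      ir <- synthesize_ir(
        transform_profile(prof, "ecological", 3, fb$sample_rate),
        fb, seed = 100 * case + s
      )
      estimate_decay_profile(ir, fb)$band_rt60
    })
    rel <- abs(rowMeans(est) / sm - 1)
    expect_lt(mean(rel), 0.10)
    expect_lt(max(rel), 0.20)
  }
})

test_that("estimating a reversed IR flags invalid band fits", {
  fb <- small_fb()
  prof <- decay_profile(rep(1.0, fb$n_bands))
  ir <- synthesize_ir(transform_profile(prof, "time_reversed", 2,
                                        fb$sample_rate), fb, seed = 3)
  est <- estimate_decay_profile(ir, fb)
  expect_false(attr(est, "valid"))
})

test_that("real-world-like IRs hit the broadband RT60 target", {
  fb <- design_filterbank(32, 20, 10e3, 20e3)
  rts <- vapply(1:4, function(s) {
    as.numeric(measure_rt60(synth_real_ir(fb, 1.0686, seed = s)))
  }, numeric(1))
  expect_equal(mean(rts), 1.0686, tolerance = 0.1)
})

test_that("envelope/filterbank mismatches error", {
  fb <- small_fb()
  prof <- decay_profile(rep(1, 8))
  env <- transform_profile(prof, "ecological", 1, fb$sample_rate)
  expect_error(synthesize_ir(env, fb), "band counts")
})
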