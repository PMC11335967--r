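# Small fixtures shared across tests. Everything is generated in code;
# sizes are kept small so the whole suite runs quickly.

small_fb <- function() design_filterbank(16, 50, 6e3, 16e3)

# iid-noise epoch set with a given size and balanced real/fake labels
noise_epochs <- function(n_trials = 20, n_ch = 8, n_t = 60, sfreq = 100,
                         t0 = -400, seed = 1) {
  withr::with_seed(seed, {
    dat <- array(rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t))
    epoch_set(
      dat, seq(t0, by = 1000 / sfreq, length.out = n_t),
      sprintf("ch%02d", seq_len(n_ch)), sfreq,
      tibble::tibble(class = rep(c("real", "fake"), length.out = n_trials))
    )
  })
}

# epochs with a clean class difference on some channels/samples
separable_epochs <- function(n_trials = 20, n_ch = 6, n_t = 40, gap = 5,
                             seed = 2) {
  ep <- noise_epochs(n_trials, n_ch, n_t, seed = seed)
  real <- ep$labels$class == "real"
  ep$data[real, 1:2, ] <- ep$data[real, 1:2, ] + gap
  ep
}
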