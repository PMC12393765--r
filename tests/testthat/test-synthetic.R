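test_that("coupled-signal generator produces the intended components", {
  ## no fast component: the signal is the slow oscillation plus noise
  sg0 <- coupled_signal(coupled_spec(duration_s = 20, gamma_amp = 0,
                                     noise_sd = 0, seed = 1))
  sp <- Mod(fft(sg0$x))^2
  f <- (seq_along(sg0$x) - 1) / length(sg0$x) * sg0$fs
  expect_equal(f[f < 20][which.max(sp[f < 20])], 8, tolerance = 0.5)
  expect_lt(sum(sp[f > 60 & f < 100]) / sum(sp[f > 1 & f < 100]), 1e-4)

  ## fast bursts are centred on the slow troughs (lag 0)
  sg <- coupled_signal(coupled_spec(duration_s = 20, noise_sd = 0, seed = 2))
  env <- as.numeric(extract_amplitude(sg$x, sg$fs, 80, 20))
  t_ms <- (seq_along(env) - 1) / sg$fs * 1000
  template <- numeric(length(env))
  for (tc in sg$trough_times_ms) {
    w <- abs(t_ms - tc) < 25
    template[w] <- template[w] + 0.5 * (1 + cos(pi * (t_ms[w] - tc) / 25))
  }
  expect_gt(cor(env, template), 0.85)
  expect_s3_class(coupled_spec(), "coupled_spec")
  expect_error(coupled_spec(fs = 100), "sampling")
  expect_error(coupled_spec(theta_period_sd_ms = 50), "exceed")
})

test_that("coupling-free noise produces no significant CFC clusters", {
  hits <- 0
  for (s in 1:10) {
    x <- null_signal(20, exponent = 1, fs = 250, seed = s)
    sig <- cfc_significance(x, 250, phase_freqs = seq(4, 10, 2),
                            amp_freqs = seq(30, 80, 10),
                            n_surrogates = 100, seed = s)
    hits <- hits + any(sig$mask)
  }
  expect_lte(hits, 2)
})

test_that("null mean vector length shrinks with duration as 1/sqrt(n)", {
  mvl_at <- function(dur) {
    mean(vapply(1:8, function(s) {
      x <- null_signal(dur, exponent = 0, fs = 250, seed = 30 + s)
      ph <- extract_phase(x, 250, 8)
      am <- extract_amplitude(x, 250, 60)
      m <- attr(am, "margin")
      keep <- (m + 1):(length(x) - m)
      mean_vector_length(ph[keep], am[keep]) / mean(am[keep])
    }, 0))
  }
  m10 <- mvl_at(10); m40 <- mvl_at(40)
  expect_equal(m10 / m40, 2, tolerance = 0.5)   # sqrt(4) scaling
})

test_that("delayed pair delays the second series by the stated amount", {
  dp <- delayed_pair(duration_s = 10, delay_ms = 20, fs = 250, seed = 1)
  k <- 20 * 250 / 1000
  expect_equal(dp$y[(k + 1):length(dp$y)], dp$x[1:(length(dp$x) - k)],
               tolerance = 1e-12)
  dp0 <- delayed_pair(duration_s = 5, delay_ms = 0, fs = 250, seed = 1)
  expect_identical(dp0$x, dp0$y)
})
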