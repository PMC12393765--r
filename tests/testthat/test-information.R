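test_that("spike-to-rate kernels have the documented shape and mass", {
  r <- spikes_to_rate(100, duration_ms = 1000, dt_ms = 1, timescale_ms = 5)
  expect_true(all(r$values[1:100] == 0))          # causal: nothing before
  i0 <- 101                                        # spike lands in bin 101
  expect_equal(r$values[i0], 1)
  expect_equal(r$values[i0 + 5], exp(-1), tolerance = 0.01)
  ## integral identity: n_spikes x discrete kernel mass
  set.seed(1)
  st <- runif(200, 0, 800)
  r2 <- spikes_to_rate(st, duration_ms = 1000, dt_ms = 1)
  kmass <- sum(exp(-(0:200) / 5))
  expect_equal(sum(r2$values), 200 * kmass, tolerance = 0.001)

  g <- spikes_to_rate(500, duration_ms = 1000, dt_ms = 1, kernel = "gaussian")
  expect_equal(which.max(g$values), 501, tolerance = 1)
  expect_equal(max(g$values), 1, tolerance = 1e-6)
})

test_that("kNN mutual information matches the Gaussian closed form", {
  set.seed(2)
  n <- 1e4
  x <- rnorm(n)
  for (rho in c(0.2, 0.5, 0.8)) {
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mi <- mutual_information(x, y)
    expect_equal(mi, -0.5 * log(1 - rho^2), tolerance = 0.1)
    ## symmetry within 5%
    expect_equal(mutual_information(y, x), mi, tolerance = 0.05)
  }
  ## independence: near zero; invariance under monotone transforms
  z <- rnorm(5000)
  expect_lt(abs(mutual_information(rnorm(5000), z)), 0.05)
  ## invariant under strictly monotone marginal transformations
  y8 <- 0.8 * x + 0.6 * rnorm(n)
  expect_equal(mutual_information(exp(x), y8), mutual_information(x, y8),
               tolerance = 0.06)
  expect_error(mutual_information(rep(1, 100), rnorm(100)), "constant")
})

test_that("lagged MI recovers an imposed delay", {
  set.seed(3)
  v <- as.numeric(band_filter(rnorm(4000), 200, 1, 40))
  rs <- function(values) structure(list(values = values, dt_ms = 5,
                                        kernel = "exponential",
                                        timescale_ms = 5),
                                   class = "rate_series")
  lag_samples <- 4                        # 20 ms at dt = 5 ms
  input <- rs(v[1:3500])
  output <- rs(c(rep(0, lag_samples), v)[1:3500])
  res <- lagged_mi(input, output, lags_ms = seq(-50, 50, 5), subsample_ms = 5)
  expect_equal(res$max_lag_ms, 20)
  expect_equal(res$max_mi, max(res$mi_curve))
  ## unrelated white noise: flat curve near zero
  res0 <- lagged_mi(rs(rnorm(3000)), rs(rnorm(3000)),
                    lags_ms = seq(-20, 20, 10), subsample_ms = 5)
  expect_lt(max(abs(res0$mi_curve)), 0.05)
  expect_error(lagged_mi(rs(rnorm(50)), rs(rnorm(50)), lags_ms = 1000),
               "lag")
})

test_that("downstream CFC of the PC rate series is kernel-independent", {
  r <- cached_desk_run("theta_ping")
  pf <- model_phase_freqs(); af <- seq(20, 80, 10)
  for (kern in c("exponential", "gaussian")) {
    rate <- spikes_to_rate(r$pc_raster$t_ms, r$duration_s * 1000, dt_ms = 1,
                           kernel = kern,
                           timescale_ms = if (kern == "gaussian") 1 else 5)
    sig <- cfc_significance(rate$values, 1000, pf, af, n_surrogates = 100,
                            seed = 7)
    expect_true(any(sig$mask))
  }
})
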