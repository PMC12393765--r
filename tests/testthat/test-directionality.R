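test_that("complex coherence obeys identity, bias, and bound contracts", {
  set.seed(1)
  fs <- 250
  x <- as.numeric(band_filter(rnorm(30 * fs), fs, 2, 60))
  C <- complex_coherence(x, x, fs)
  keep <- C$freqs > 4 & C$freqs < 55
  expect_true(all(abs(Mod(C$C[keep]) - 1) < 1e-9))
  expect_true(all(Mod(C$C) <= 1 + 1e-9))

  ## independent white noise: mean |C| ~ 1/sqrt(N_segments)
  set.seed(2)
  y <- rnorm(length(x))
  Cn <- complex_coherence(x, rnorm(length(x)), fs)
  expect_equal(mean(Mod(Cn$C[keep])),
               sqrt(pi) / 2 / sqrt(Cn$n_segments), tolerance = 0.25)

  expect_error(complex_coherence(x[1:100], x[1:99], fs), "length")
  expect_error(complex_coherence(x[1:300], x[1:300], fs), "segments")
})

test_that("phase slope index sign is pinned by a pure delay", {
  dp <- delayed_pair(duration_s = 30, delay_ms = 10, fs = 250, seed = 2)
  C <- complex_coherence(dp$x, dp$y, dp$fs)
  psi <- phase_slope_index(C, 15, beta = 5)
  expect_gt(psi, 0)                       # x leads y -> positive
  Cr <- complex_coherence(dp$y, dp$x, dp$fs)
  expect_equal(phase_slope_index(Cr, 15, beta = 5), -psi, tolerance = 1e-9)

  ## zero delay: |PSI| below the null 95th percentile from delayed fixtures
  d0 <- delayed_pair(duration_s = 30, delay_ms = 0, fs = 250, seed = 3)
  C0 <- complex_coherence(d0$x, d0$y, d0$fs)
  expect_lt(abs(phase_slope_index(C0, 15, beta = 5)), 0.05)

  expect_error(phase_slope_index(C, 1, beta = 5), "grid")
})

test_that("CFD map is masked by the normalised CFC", {
  sg <- coupled_signal(coupled_spec(duration_s = 30, lag_ms = 10, seed = 4))
  cfc <- cfc_comodulogram(sg$x, sg$fs)
  cfd <- cfd_map(sg$x, sg$fs, cfc = cfc)
  m <- cfd$meta$cfc_mask
  expect_equal(max(m, na.rm = TRUE), 1)
  ## cells with (near) zero CFC are (near) zeroed in the CFD
  weak <- which(m < 1e-3)
  expect_true(all(abs(cfd$values[weak]) < 1e-2, na.rm = TRUE))
  expect_error(cfd_avg(cfd, cfc_comodulogram(sg$x, sg$fs,
                                             phase_freqs = 2:10)), "grids")
})

test_that("CFD_avg summarises the retained high-CFC cells", {
  v <- matrix(runif(25), 5, 5)
  cfc <- thetagamma:::new_comodulogram(1:5, 1:5, v)
  cfd <- thetagamma:::new_comodulogram(1:5, 1:5, matrix(0.3, 5, 5))
  expect_equal(cfd_avg(cfd, cfc), 0.3)
  cfc0 <- thetagamma:::new_comodulogram(1:5, 1:5, matrix(NA_real_, 5, 5))
  expect_error(cfd_avg(cfd, cfc0))
})

test_that("synthetic lag maps to the CFD sign and is quantile-stable", {
  pos <- coupled_signal(coupled_spec(duration_s = 40, lag_ms = 10, seed = 5))
  neg <- coupled_signal(coupled_spec(duration_s = 40, lag_ms = -10, seed = 5))
  cp <- cfc_comodulogram(pos$x, pos$fs)
  dp <- cfd_map(pos$x, pos$fs, cfc = cp)
  cn <- cfc_comodulogram(neg$x, neg$fs)
  dn <- cfd_map(neg$x, neg$fs, cfc = cn)
  expect_gt(cfd_avg(dp, cp), 0)
  expect_lt(cfd_avg(dn, cn), 0)
  ## sign is stable across alternative retention quantiles
  for (q in c(0.95, 0.9, 0.85)) {
    expect_gt(cfd_avg(dp, cp, quantile = q), 0)
    expect_lt(cfd_avg(dn, cn, quantile = q), 0)
  }
  ## time reversal flips the directionality
  cr <- cfc_comodulogram(rev(pos$x), pos$fs)
  dr <- cfd_map(rev(pos$x), pos$fs, cfc = cr)
  expect_lt(cfd_avg(dr, cr), 0)
})

test_that("two-tailed CFD significance returns no clusters on null noise", {
  hits <- 0
  for (s in 1:4) {
    x <- null_signal(24, exponent = 1, fs = 250, seed = 100 + s)
    sig <- cfd_significance(x, 250, phase_freqs = seq(4, 10, 2),
                            amp_freqs = seq(30, 80, 10),
                            n_surrogates = 100, seed = s)
    hits <- hits + any(sig$mask)
  }
  expect_lte(hits, 1)
  ## all-zero CFD trivially yields an empty mask
  v0 <- thetagamma:::new_comodulogram(1:3, 1:3, matrix(0, 3, 3))
  surr0 <- lapply(1:20, function(s) {
    set.seed(s); thetagamma:::new_comodulogram(1:3, 1:3,
      matrix(rnorm(9, 0, 0.1), 3, 3))
  })
  up <- cluster_significance(v0, surr0, tail = "upper")
  lo <- cluster_significance(v0, surr0, tail = "lower")
  expect_false(any(up$mask | lo$mask))
})
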