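fs <- 500

test_that("zero-phase band filter passes the band and rejects outside it", {
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  y <- band_filter(x, fs, 8, 12)
  m <- attr(y, "margin")
  keep <- (m + 1):(length(y) - m)
  ## 10 Hz retained with unity gain and no phase shift, 60 Hz removed
  expect_equal(stats::sd(y[keep] - sin(2 * pi * 10 * t)[keep]), 0,
               tolerance = 0.02)
  expect_error(band_filter(x, fs, 100, 260), "Nyquist")
  expect_error(band_filter(x, fs, 12, 8), "passband")
})

test_that("analytic-signal phase and amplitude behave canonically", {
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t)
  ph <- extract_phase(x, fs, 8)
  m <- attr(ph, "margin")
  keep <- (m + 1):(length(ph) - m)
  slope <- mean(diff(unwrap_phase <- cumsum(c(ph[keep][1],
    ((diff(ph[keep]) + pi) %% (2 * pi)) - pi))))
  expect_equal(slope * fs, 2 * pi * 8, tolerance = 0.01)
  ## negated signal: phase shifted by pi
  ph2 <- extract_phase(-x, fs, 8)
  dd <- (ph2[keep] - ph[keep]) %% (2 * pi)
  expect_equal(mean(abs(dd - pi) < 0.05), 1, tolerance = 0.01)

  am <- extract_amplitude(3 * sin(2 * pi * 60 * t), fs, 60)
  expect_equal(mean(am[keep]), 3, tolerance = 0.05)
  expect_lt(max(abs(am[keep] - 3)) / 3, 0.05)   # ripple under 5%
  expect_equal(max(extract_amplitude(numeric(length(t)), fs, 60)), 0)
})

test_that("envelope of an AM carrier recovers the modulator", {
  t <- (0:(30 * fs - 1)) / fs
  mod <- 1 + 0.7 * cos(2 * pi * 8 * t)
  x <- mod * sin(2 * pi * 80 * t)
  am <- extract_amplitude(x, fs, 80, halfwidth = 10)
  m <- attr(am, "margin")
  keep <- (m + 1):(length(am) - m)
  expect_gt(cor(am[keep], mod[keep]), 0.95)
})

test_that("mean vector length matches analytic cases", {
  phi <- seq(0, 2 * pi * 500, length.out = 5e5 + 1)[-1]
  expect_equal(mean_vector_length(phi %% (2 * pi), rep(1, length(phi))), 0,
               tolerance = 1e-3)
  ## A = 1 + cos(phi) -> |integral (1+cos)e^{i phi}|/(2 pi) = 1/2
  expect_equal(mean_vector_length(phi, 1 + cos(phi)), 0.5, tolerance = 0.005)
  ## invariance under global rotation; linear scaling with gain
  set.seed(1)
  a <- rexp(1000); p <- runif(1000, -pi, pi)
  expect_equal(mean_vector_length(p + 1.1, a), mean_vector_length(p, a),
               tolerance = 1e-12)
  expect_equal(mean_vector_length(p, 3 * a), 3 * mean_vector_length(p, a),
               tolerance = 1e-12)
  expect_error(mean_vector_length(p, a[-1]), "length")
})

test_that("phase-split surrogates swap segments and preserve content", {
  x <- sin(seq(0, 20 * pi, length.out = 1000))
  s <- phase_split_surrogate(x, split = 500)
  expect_identical(s, c(x[501:1000], x[1:500]))
  s2 <- phase_split_surrogate(x, seed = 3)
  expect_identical(sort(s2), sort(x))
  expect_error(phase_split_surrogate(x, split = 10), "segment")
  ## band-averaged power spectrum preserved within 5%
  xr <- null_signal(4, exponent = 1, fs = 250, seed = 5)
  sr <- phase_split_surrogate(xr, seed = 6)
  pw <- function(z) {
    sp <- Mod(fft(z))^2
    n <- length(z)
    f <- (seq_len(n) - 1) / n * 250
    tapply(sp[f > 1 & f < 100], cut(f[f > 1 & f < 100], 8), mean)
  }
  expect_equal(as.numeric(pw(sr)), as.numeric(pw(xr)), tolerance = 0.05)
})

test_that("cluster labelling agrees with a label-propagation oracle", {
  ## independent oracle: iterate neighbourhood-minimum label propagation
  ## to a fixpoint, which yields the 4-connected components exactly
  propagate_oracle <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    lab <- matrix(seq_along(m), nr, nc)
    lab[!m] <- 0L
    repeat {
      old <- lab
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!m[i, j]) next
        nb <- c(lab[i, j],
                if (i > 1) lab[i - 1, j], if (i < nr) lab[i + 1, j],
                if (j > 1) lab[i, j - 1], if (j < nc) lab[i, j + 1])
        lab[i, j] <- min(nb[nb > 0])
      }
      if (identical(lab, old)) break
    }
    lab
  }
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(11 * 9) > 0.6, 11, 9)
    lab <- label_clusters(m)
    ora <- propagate_oracle(m)
    idx <- which(m)
    ## identical partitions (labels are a bijection between the two)
    expect_equal(length(unique(lab[idx])), length(unique(ora[idx])))
    expect_true(all(tapply(ora[idx], lab[idx],
                           function(z) length(unique(z))) == 1))
    expect_true(all(tapply(lab[idx], ora[idx],
                           function(z) length(unique(z))) == 1))
    ## cluster scores agree on a random value matrix
    v <- matrix(rexp(length(m)), nrow(m), ncol(m))
    sc1 <- sort(as.numeric(tapply(v[idx], lab[idx], sum)))
    sc2 <- sort(as.numeric(tapply(v[idx], ora[idx], sum)))
    expect_equal(sc1, sc2)
  }
})

test_that("cluster significance scores clusters by summed value", {
  ## hand-built 5x5 comodulogram with two clusters
  v <- matrix(0, 5, 5)
  v[1:2, 1] <- c(5, 4)       # cluster A, score 9
  v[4:5, 4:5] <- 2           # cluster B, score 8
  obs <- thetagamma:::new_comodulogram(1:5, 1:5, v)
  surr <- lapply(1:50, function(s) {
    set.seed(s)
    thetagamma:::new_comodulogram(1:5, 1:5, matrix(abs(rnorm(25, 0, 0.5)), 5, 5))
  })
  sig <- cluster_significance(obs, surr, quantile = 0.99)
  expect_true(all(sig$mask[v > sig$k_th]))
  expect_setequal(round(sort(sig$cluster_scores)), c(8, 9))
  ## all-below-threshold observation gives an empty mask
  obs0 <- thetagamma:::new_comodulogram(1:5, 1:5, matrix(0, 5, 5))
  expect_false(any(cluster_significance(obs0, surr)$mask))
  ## grid mismatch is an error
  obs2 <- thetagamma:::new_comodulogram(1:4, 1:5, v[1:4, ])
  expect_error(cluster_significance(obs2, surr), "grid")
})

test_that("a single suprathreshold cell forms its own cluster", {
  v <- matrix(0, 4, 4); v[2, 3] <- 10
  obs <- thetagamma:::new_comodulogram(1:4, 1:4, v)
  surr <- lapply(1:50, function(s) {
    set.seed(100 + s)
    thetagamma:::new_comodulogram(1:4, 1:4, matrix(abs(rnorm(16, 0, 0.3)), 4, 4))
  })
  sig <- cluster_significance(obs, surr)
  expect_equal(sum(sig$mask), 1L)
  expect_equal(sig$cluster_scores, 10)
})
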