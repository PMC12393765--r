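#' Specification for a synthetic theta-gamma coupled signal
#'
#' Describes a 1-D field-potential-like test signal: a slow (~8 Hz) component
#' built by concatenating sinusoidal cycles whose periods are drawn from a
#' Gaussian, plus a fast sinusoidal component whose amplitude is gated by a
#' unimodal envelope centred on each slow-cycle trough, shifted by a
#' configurable lag. Positive `lag_ms` places the fast bursts after the
#' trough (slow leads fast); negative lag places them before (fast leads).
#'
#' @param duration_s signal duration in seconds.
#' @param theta_amp slow-component amplitude (arbitrary units).
#' @param theta_period_mean_ms,theta_period_sd_ms cycle period distribution (ms).
#' @param gamma_freq fast-component frequency (Hz).
#' @param gamma_amp fast-component amplitude; default 0.3 x `theta_amp`.
#' @param lag_ms lag of the fast bursts relative to the slow trough (ms).
#' @param envelope_halfwidth_ms half-width of the raised-cosine gating window (ms).
#' @param noise_sd additive Gaussian noise sd; default 0.1 x `theta_amp`.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return a list of class `"coupled_spec"`.
#' @export
coupled_spec <- function(duration_s = 60, theta_amp = 10,
                         theta_period_mean_ms = 125, theta_period_sd_ms = 16,
                         gamma_freq = 80, gamma_amp = 0.3 * theta_amp,
                         lag_ms = 0, envelope_halfwidth_ms = 25,
                         noise_sd = 0.1 * theta_amp, fs = 1000, seed = 1L) {
  assert_positive(duration_s, "duration_s")
  assert_positive(fs, "fs")
  if (fs < 4 * gamma_freq) {
    stop("sampling rate must be at least 4 x gamma_freq", call. = FALSE)
  }
  if (theta_period_mean_ms <= 3 * theta_period_sd_ms) {
    stop("theta_period_mean_ms must exceed 3 x theta_period_sd_ms", call. = FALSE)
  }
  structure(list(duration_s = duration_s, theta_amp = theta_amp,
                 theta_period_mean_ms = theta_period_mean_ms,
                 theta_period_sd_ms = theta_period_sd_ms,
                 gamma_freq = gamma_freq, gamma_amp = gamma_amp,
                 lag_ms = lag_ms,
                 envelope_halfwidth_ms = envelope_halfwidth_ms,
                 noise_sd = noise_sd, fs = fs, seed = as.integer(seed)),
            class = "coupled_spec")
}

#' Generate a synthetic theta-gamma coupled signal
#'
#' The slow component concatenates full sinusoidal cycles (phase-continuous
#' at the joins) with periods `N(mean, sd^2)`; the fast component is a
#' sinusoid at `gamma_freq` multiplied by a raised-cosine window centred on
#' each slow trough shifted by `lag_ms`. The two are summed with additive
#' Gaussian noise.
#'
#' @param spec a [coupled_spec()].
#' @return list with `x` (the signal), `fs`, `trough_times_ms`, and `spec`.
#' @export
coupled_signal <- function(spec) {
  stopifnot(inherits(spec, "coupled_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  dur_ms <- spec$duration_s * 1000
  n <- round(dur_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) / fs * 1000

  ## sample cycle periods until they cover the full duration (+ margin)
  periods <- numeric(0)
  total <- 0
  while (total < dur_ms + 4 * spec$theta_period_mean_ms) {
    p <- rnorm(64, spec$theta_period_mean_ms, spec$theta_period_sd_ms)
    p <- p[p > 3 * spec$theta_period_sd_ms]  # guard against degenerate cycles
    periods <- c(periods, p)
    total <- sum(periods)
  }
  starts <- c(0, cumsum(periods))

  ## each segment spans one full cycle from trough to trough, so the
  ## period jitter is symmetric in time around every trough (coupling
  ## events sit in the middle of their deterministic window)
  cyc <- findInterval(t_ms, starts)
  ph <- 3 * pi / 2 + 2 * pi * (cyc - 1 + (t_ms - starts[cyc]) / periods[cyc])
  theta <- spec$theta_amp * sin(ph)

  troughs <- starts[starts < dur_ms]

  env <- numeric(n)
  w <- spec$envelope_halfwidth_ms
  for (tc in troughs + spec$lag_ms) {
    i0 <- max(1L, ceiling((tc - w) * fs / 1000) + 1L)
    i1 <- min(n, floor((tc + w) * fs / 1000) + 1L)
    if (i1 >= i0) {
      tt <- t_ms[i0:i1] - tc
      env[i0:i1] <- env[i0:i1] + 0.5 * (1 + cos(pi * tt / w))
    }
  }
  gamma <- spec$gamma_amp * env * sin(2 * pi * spec$gamma_freq * t_ms / 1000)
  x <- theta + gamma + rnorm(n, 0, spec$noise_sd)
  list(x = x, fs = fs, trough_times_ms = troughs, spec = spec)
}

#' Broadband signal and a delayed copy
#'
#' Fixture used to pin the sign convention of the phase slope index: the
#' second series is the first delayed (circularly) by `delay_ms`, so the
#' first leads for positive delays.
#'
#' @param duration_s duration (s).
#' @param delay_ms delay of `y` relative to `x` (ms).
#' @param band passband (Hz) of the underlying filtered white noise.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return list with `x`, `y`, `fs`.
#' @export
delayed_pair <- function(duration_s = 30, delay_ms = 10, band = c(2, 45),
                         fs = 250, seed = 1L) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- band_filter(rnorm(n), fs, band[1], band[2])
  k <- round(delay_ms * fs / 1000)
  y <- if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
  list(x = x, y = y, fs = fs)
}

#' Coupling-free noise with a configurable power-law spectrum
#'
#' Used to calibrate the false-positive rate of the surrogate + cluster
#' significance procedures: the signal has no phase-amplitude coupling by
#' construction.
#'
#' @param duration_s duration (s).
#' @param exponent spectral exponent alpha in `S(f) ~ 1/f^alpha` (0 = white).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return numeric series of length `duration_s * fs`.
#' @export
null_signal <- function(duration_s = 30, exponent = 1, fs = 250, seed = 1L) {
  set.seed(seed)
  n <- round(duration_s * fs)
  wh <- rnorm(n)
  if (exponent == 0) return(wh)
  xf <- fft(wh)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)             # two-sided frequency magnitude
  scale <- c(0, (f[-1])^(-exponent / 2))
  Re(fft(xf * scale, inverse = TRUE)) / n
}
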