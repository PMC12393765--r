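## Phase/amplitude extraction, mean-vector-length CFC comodulograms,
## phase-split surrogates and cluster-based significance.

## Next 5-smooth length >= n (fast FFT sizes).
good_fft_length <- function(n) stats::nextn(n, c(2, 3, 5))

## Largest 5-smooth length <= n.
prev_good_length <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m - 1
  }
}

## Shared filtering engine: caches the FFT of the zero-padded signal and
## returns band-limited series with one inverse FFT per band. The frequency
## response is a frequency-sampled linear-phase band-pass: unity in
## [f_lo, f_hi] with raised-cosine transitions of width `tw` on either side,
## i.e. exactly zero phase. `analytic = TRUE` folds the Hilbert weights in,
## returning the complex analytic band signal directly.
band_engine <- function(x, fs) {
  n <- length(x)
  L <- good_fft_length(n + round(fs))      # pad: keeps wraparound in the margin
  X <- fft(c(x, numeric(L - n)))
  f <- (seq_len(L) - 1) * fs / L
  f_fold <- pmin(f, fs - f)
  pos <- f <= fs / 2                        # positive-frequency half (incl. DC)
  function(f_lo, f_hi, tw, analytic = TRUE) {
    H <- numeric(L)
    inside <- f_fold >= f_lo & f_fold <= f_hi
    H[inside] <- 1
    lo_t <- f_fold > f_lo - tw & f_fold < f_lo
    H[lo_t] <- 0.5 * (1 + cos(pi * (f_lo - f_fold[lo_t]) / tw))
    hi_t <- f_fold > f_hi & f_fold < f_hi + tw
    H[hi_t] <- 0.5 * (1 + cos(pi * (f_fold[hi_t] - f_hi) / tw))
    if (analytic) {
      H[!pos] <- 0
      H[pos] <- H[pos] * 2
      H[1] <- H[1] / 2
      y <- fft(X * H, inverse = TRUE)[1:n] / L
    } else {
      y <- Re(fft(X * H, inverse = TRUE)[1:n]) / L
    }
    attr(y, "margin") <- min(ceiling(2 * fs / tw), n %/% 3)
    y
  }
}

#' Zero-phase band-pass filter
#'
#' Frequency-sampled linear-phase band-pass (unity gain in the passband,
#' raised-cosine transitions) applied in the frequency domain, so the output
#' has exactly zero phase shift. The effective impulse-response half-length
#' is returned as attribute `"margin"` so callers can discard edge samples
#' before computing metrics.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi passband edges (Hz).
#' @param transition transition width (Hz); default half the passband width,
#'   at least 1 Hz.
#' @return filtered series with attribute `"margin"` (samples).
#' @export
band_filter <- function(x, fs, f_lo, f_hi, transition = NULL) {
  nyq <- fs / 2
  if (f_hi >= nyq) stop("upper band edge exceeds the Nyquist frequency", call. = FALSE)
  if (f_lo <= 0 || f_hi <= f_lo) stop("invalid passband", call. = FALSE)
  tw <- transition %||% max(0.5 * (f_hi - f_lo), 1)
  band_engine(x, fs)(f_lo, f_hi, tw, analytic = FALSE)
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x real numeric series.
#' @return complex series whose real part is `x` and whose imaginary part is
#'   the Hilbert transform of `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal in a narrow band
#'
#' Band-pass filters around `f_phase` and returns the analytic-signal phase.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param f_phase centre frequency (Hz).
#' @param halfwidth half-bandwidth of the filter (Hz), default 2.
#' @return phase series in `(-pi, pi]`, with the filter margin attribute.
#' @export
extract_phase <- function(x, fs, f_phase, halfwidth = 2, engine = NULL) {
  if (length(x) / fs < 10 / f_phase) {
    stop("signal shorter than 10 cycles of f_phase", call. = FALSE)
  }
  eng <- engine %||% band_engine(x, fs)
  z <- eng(max(f_phase - halfwidth, 0.25), f_phase + halfwidth,
           tw = max(halfwidth, 1))
  ph <- Arg(z)
  attr(ph, "margin") <- attr(z, "margin")
  ph
}

#' Instantaneous amplitude envelope of a signal in a band
#'
#' Band-pass filters around `f_amp` and returns the analytic-signal modulus.
#' The bandwidth must exceed twice the modulating frequency of interest for
#' the envelope to carry the modulation sidebands.
#'
#' @inheritParams extract_phase
#' @param f_amp centre frequency (Hz).
#' @param halfwidth half-bandwidth of the filter (Hz).
#' @return non-negative envelope series, with the filter margin attribute.
#' @export
extract_amplitude <- function(x, fs, f_amp, halfwidth = 10, engine = NULL) {
  eng <- engine %||% band_engine(x, fs)
  f_lo <- max(f_amp - halfwidth, 0.25)
  f_hi <- min(f_amp + halfwidth, fs / 2 * 0.999)
  z <- eng(f_lo, f_hi, tw = 2)
  am <- Mod(z)
  attr(am, "margin") <- attr(z, "margin")
  am
}

#' Mean vector length (phase-amplitude coupling statistic)
#'
#' The modulus of the time average of `A(t) * exp(i * phi(t))`. Radially
#' symmetric trajectories (no coupling) give values near zero.
#'
#' @param phase phase series (radians).
#' @param amplitude amplitude series, same length.
#' @return non-negative scalar.
#' @export
mean_vector_length <- function(phase, amplitude) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude series must have equal length", call. = FALSE)
  }
  Mod(mean(amplitude * exp(1i * phase)))
}

default_phase_freqs <- function() seq(2, 20, by = 1)
default_amp_freqs <- function() seq(20, 150, by = 5)

#' Frequency grids for simulated population signals
#'
#' Theta-focused comodulogram grids used for the model's somatic current and
#' potential series: the phase axis covers the theta range (4-12 Hz). The
#' lowest phase bands of the full grid are dominated by slow population
#' drift (finite-size noise in the averaged currents) rather than by the
#' theta rhythm, so model analyses restrict the phase axis to theta.
#' @export
#' @rdname model_freqs
model_phase_freqs <- function() seq(4, 12, by = 1)

#' @export
#' @rdname model_freqs
model_amp_freqs <- function() seq(20, 120, by = 5)

## Fixed amplitude-filter half-bandwidth (Hz): 20 Hz full width passes the
## modulation sidebands of theta-range phase frequencies while keeping rows
## of the (unnormalised) mean-vector-length comodulogram comparable.
default_amp_halfwidth <- function() 10

new_comodulogram <- function(phase_freqs, amp_freqs, values, mask = NULL,
                             meta = list()) {
  stopifnot(nrow(values) == length(phase_freqs),
            ncol(values) == length(amp_freqs))
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
                 values = values, mask = mask, meta = meta),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d phase x %d amplitude frequencies (%s)\n",
              length(x$phase_freqs), length(x$amp_freqs),
              x$meta$kind %||% "CFC"))
  pk <- comodulogram_peak(x)
  cat(sprintf("  peak |value| %.4g at (%g Hz, %g Hz)\n",
              x$values[pk[1], pk[2]], x$phase_freqs[pk[1]], x$amp_freqs[pk[2]]))
  invisible(x)
}

comodulogram_peak <- function(com) {
  which(abs(com$values) == max(abs(com$values)), arr.ind = TRUE)[1, ]
}

## Filter the signal once per needed band; returns phase list, amplitude
## cache keyed by "f_amp/halfwidth", and the common edge margin.
precompute_phase_amp <- function(x, fs, phase_freqs, amp_freqs,
                                 phase_halfwidth = 2,
                                 amp_halfwidth = default_amp_halfwidth()) {
  eng <- band_engine(x, fs)
  phases <- lapply(phase_freqs, function(f)
    extract_phase(x, fs, f, phase_halfwidth, engine = eng))
  amps <- lapply(amp_freqs, function(fa) {
    if (fa - amp_halfwidth >= fs / 2) return(NULL)
    extract_amplitude(x, fs, fa, amp_halfwidth, engine = eng)
  })
  margin <- max(c(vapply(phases, function(p) attr(p, "margin"), 0),
                  vapply(Filter(Negate(is.null), amps),
                         function(a) attr(a, "margin"), 0)))
  list(phases = phases, amps = amps, margin = margin)
}

#' Cross-frequency-coupling comodulogram (mean vector length)
#'
#' Computes the mean vector length for every (phase frequency, amplitude
#' frequency) pair on a grid. The amplitude band uses a fixed half-width
#' (default 10 Hz, i.e. 20 Hz full width) wide enough to retain the
#' modulation sidebands of theta-range phase frequencies while keeping the
#' unnormalised statistic comparable across cells; one filter-margin is
#' discarded at each edge before averaging.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param phase_freqs,amp_freqs frequency grids (Hz).
#' @param phase_halfwidth half-bandwidth of the phase filters (Hz).
#' @param amp_halfwidth half-bandwidth of the amplitude filters (Hz).
#' @return a `comodulogram` with non-negative `values`.
#' @export
cfc_comodulogram <- function(x, fs, phase_freqs = default_phase_freqs(),
                             amp_freqs = default_amp_freqs(),
                             phase_halfwidth = 2,
                             amp_halfwidth = default_amp_halfwidth(),
                             pre = NULL) {
  pre <- pre %||% precompute_phase_amp(x, fs, phase_freqs, amp_freqs,
                                       phase_halfwidth, amp_halfwidth)
  n <- length(x)
  keep <- (pre$margin + 1):(n - pre$margin)
  vals <- matrix(NA_real_, length(phase_freqs), length(amp_freqs))
  for (i in seq_along(phase_freqs)) {
    ph <- pre$phases[[i]][keep]
    for (j in seq_along(amp_freqs)) {
      if (is.null(pre$amps[[j]])) next
      vals[i, j] <- mean_vector_length(ph, pre$amps[[j]][keep])
    }
  }
  new_comodulogram(phase_freqs, amp_freqs, vals,
                   meta = list(kind = "CFC", fs = fs,
                               phase_halfwidth = phase_halfwidth,
                               amp_halfwidth = amp_halfwidth,
                               margin = pre$margin))
}

#' Phase-split surrogate of a phase series
#'
#' Cuts the series at a random point and swaps the two segments (equivalent
#' to a circular rotation), destroying the phase-amplitude alignment while
#' preserving the sample multiset and, to good approximation, the spectrum.
#'
#' @param phase numeric series.
#' @param seed integer seed; ignored when `split` is given.
#' @param min_frac minimum segment length as a fraction of the series.
#' @param split optional explicit split index in
#'   `[min_frac * n, (1 - min_frac) * n]`.
#' @return surrogate series (second segment followed by the first).
#' @export
phase_split_surrogate <- function(phase, seed = NULL, min_frac = 0.1,
                                  split = NULL) {
  n <- length(phase)
  lo <- ceiling(min_frac * n); hi <- floor((1 - min_frac) * n)
  if (lo >= hi) stop("series too short for the minimum segment length", call. = FALSE)
  if (is.null(split)) {
    if (!is.null(seed)) set.seed(seed)
    split <- sample(lo:hi, 1L)
  } else if (split < lo || split > hi) {
    stop("split point violates the minimum segment length", call. = FALSE)
  }
  c(phase[(split + 1):n], phase[1:split])
}

## Surrogate CFC comodulograms. Swapping the phase series at split k is a
## circular rotation, so the surrogate mean vector for every rotation is one
## lag of the circular cross-correlation between A(t) and exp(i*phi(t)),
## computed for all lags at once with FFTs.
cfc_surrogates <- function(x, fs, n_surrogates = 200,
                           phase_freqs = default_phase_freqs(),
                           amp_freqs = default_amp_freqs(),
                           phase_halfwidth = 2,
                           amp_halfwidth = default_amp_halfwidth(),
                           min_frac = 0.1, seed = 1L, pre = NULL) {
  if (is.null(pre)) {
    pre <- precompute_phase_amp(x, fs, phase_freqs, amp_freqs,
                                phase_halfwidth, amp_halfwidth)
  }
  n <- length(x)
  keep <- (pre$margin + 1):(n - pre$margin)
  keep <- keep[seq_len(prev_good_length(length(keep)))]  # fast FFT length
  m <- length(keep)
  set.seed(seed)
  lo <- ceiling(min_frac * m); hi <- floor((1 - min_frac) * m)
  splits <- sample(lo:hi, n_surrogates, replace = TRUE)

  e_fft <- lapply(pre$phases, function(p) Conj(fft(exp(1i * p[keep]))))
  a_fft <- lapply(pre$amps, function(a)
    if (is.null(a)) NULL else fft(a[keep]))
  out <- vector("list", n_surrogates)
  vals <- array(NA_real_, c(length(phase_freqs), length(amp_freqs), n_surrogates))
  for (i in seq_along(phase_freqs)) {
    for (j in seq_along(amp_freqs)) {
      if (is.null(a_fft[[j]])) next
      ## r[k+1] = sum_t A(t) * conj(E(t + k)), E = exp(i*phi); the modulus
      ## equals the surrogate mean vector length at split k (times m)
      r <- fft(a_fft[[j]] * e_fft[[i]], inverse = TRUE) / m
      vals[i, j, ] <- Mod(r[splits + 1]) / m
    }
  }
  for (s in seq_len(n_surrogates)) {
    out[[s]] <- new_comodulogram(phase_freqs, amp_freqs, vals[, , s],
                                 meta = list(kind = "CFC surrogate"))
  }
  out
}

#' Label 4-connected clusters of TRUE cells in a logical matrix
#'
#' @param mask logical matrix.
#' @return integer matrix of cluster labels (0 = background).
#' @export
label_clusters <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!isTRUE(mask[i, j]) || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (!isTRUE(mask[p[1], p[2]]) || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      stack <- c(stack, list(c(p[1] - 1L, p[2]), c(p[1] + 1L, p[2]),
                             c(p[1], p[2] - 1L), c(p[1], p[2] + 1L)))
    }
  }
  lab
}

cluster_scores <- function(values, mask) {
  lab <- label_clusters(mask)
  if (max(lab) == 0L) return(numeric(0))
  as.numeric(tapply(values[lab > 0], lab[lab > 0], sum))
}

#' Surrogate cluster-based significance of a comodulogram
#'
#' Pools all surrogate cell values to obtain the threshold `k_th` (the
#' `quantile` quantile, 99th percentile by default); zeroes observed values
#' below it; scores 4-connected clusters of the surviving cells by their
#' summed value; and keeps an observed cluster if its score exceeds the same
#' quantile of the surrogate cluster scores (surrogates with no cluster
#' contribute a zero score). With `tail = "lower"` everything is mirrored to
#' detect significantly negative values (used for directionality maps).
#'
#' @param observed a `comodulogram`.
#' @param surrogates list of comodulograms on the same grids.
#' @param quantile significance quantile (default 0.99).
#' @param tail `"upper"` or `"lower"`.
#' @return list with `mask` (logical matrix), `k_th`, `cluster_scores`,
#'   `surrogate_scores`, `score_threshold`.
#' @export
cluster_significance <- function(observed, surrogates, quantile = 0.99,
                                 tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  for (s in surrogates) {
    if (!identical(s$phase_freqs, observed$phase_freqs) ||
        !identical(s$amp_freqs, observed$amp_freqs)) {
      stop("surrogate grids do not match the observed comodulogram", call. = FALSE)
    }
  }
  sgn <- if (tail == "upper") 1 else -1
  obs <- sgn * observed$values
  pool <- sgn * unlist(lapply(surrogates, function(s) s$values))
  pool <- pool[is.finite(pool)]
  k_th <- stats::quantile(pool, quantile, names = FALSE)

  surr_scores <- unlist(lapply(surrogates, function(s) {
    v <- sgn * s$values
    sc <- cluster_scores(v, is.finite(v) & v > k_th)
    if (length(sc) == 0) 0 else sc
  }))
  score_th <- stats::quantile(surr_scores, quantile, names = FALSE)

  keep <- is.finite(obs) & obs > k_th
  lab <- label_clusters(keep)
  mask <- matrix(FALSE, nrow(obs), ncol(obs))
  scores <- numeric(0)
  if (max(lab) > 0L) {
    scores <- as.numeric(tapply(obs[lab > 0], lab[lab > 0], sum))
    for (cl in which(scores > score_th)) mask[lab == cl] <- TRUE
  }
  list(mask = mask, k_th = sgn * k_th, cluster_scores = sgn * scores,
       surrogate_scores = sgn * surr_scores, score_threshold = sgn * score_th)
}

#' CFC comodulogram with surrogate cluster significance
#'
#' Convenience wrapper running [cfc_comodulogram()], the phase-split
#' surrogate ensemble, and [cluster_significance()].
#'
#' @inheritParams cfc_comodulogram
#' @param n_surrogates number of phase-split surrogates.
#' @param quantile significance quantile.
#' @param seed integer seed for the surrogate splits.
#' @return the observed `comodulogram` with its `mask` field set and the
#'   significance details in `meta$significance`.
#' @export
cfc_significance <- function(x, fs, phase_freqs = default_phase_freqs(),
                             amp_freqs = default_amp_freqs(),
                             phase_halfwidth = 2,
                             amp_halfwidth = default_amp_halfwidth(),
                             n_surrogates = 200, quantile = 0.99, seed = 1L) {
  pre <- precompute_phase_amp(x, fs, phase_freqs, amp_freqs,
                              phase_halfwidth, amp_halfwidth)
  obs <- cfc_comodulogram(x, fs, phase_freqs, amp_freqs,
                          phase_halfwidth, amp_halfwidth, pre = pre)
  surr <- cfc_surrogates(x, fs, n_surrogates, phase_freqs, amp_freqs,
                         phase_halfwidth, amp_halfwidth, seed = seed, pre = pre)
  sig <- cluster_significance(obs, surr, quantile)
  obs$mask <- sig$mask
  obs$meta$significance <- sig[c("k_th", "cluster_scores", "score_threshold")]
  obs$meta$n_surrogates <- n_surrogates
  obs
}
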