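## Cross-frequency directionality: Welch complex coherence, phase slope
## index (PSI), CFC-masked CFD maps, CFD_avg, two-tailed cluster significance.

#' Spectral settings for the phase slope index
#'
#' @param beta integration bandwidth of the PSI (Hz).
#' @param segment_s Welch segment length (s); sets the frequency resolution
#'   `delta_f = 1 / segment_s`.
#' @param overlap segment overlap fraction.
#' @return list of class `"psi_spec"`.
#' @export
psi_spec <- function(beta = 5, segment_s = 1, overlap = 0.5) {
  assert_positive(beta, "beta"); assert_positive(segment_s, "segment_s")
  stopifnot(overlap >= 0, overlap < 1)
  df <- 1 / segment_s
  if (beta < 2 * df) stop("beta must be at least twice the frequency resolution",
                          call. = FALSE)
  structure(list(beta = beta, segment_s = segment_s, overlap = overlap),
            class = "psi_spec")
}

segment_starts <- function(n, nfft, hop) seq(1L, n - nfft + 1L, by = hop)

## FFTs of windowed segments, keeping only the requested frequency bins.
seg_ffts <- function(x, nfft, hop, bins, window) {
  starts <- segment_starts(length(x), nfft, hop)
  out <- matrix(0i, length(bins), length(starts))
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + nfft - 1L)] * window
    out[, s] <- fft(seg)[bins]
  }
  out
}

#' Complex coherence between two series (Welch estimate)
#'
#' `C(f) = sum_i X_i(f) Y_i(f)* / sqrt(sum_i |X_i|^2 sum_i |Y_i|^2)` over
#' Hann-windowed overlapping segments.
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate (Hz).
#' @param spec a [psi_spec()].
#' @param min_segments minimum admissible number of segments.
#' @return list of class `"coherence"` with `freqs`, `C`, `n_segments`, `df`.
#' @export
complex_coherence <- function(x, y, fs, spec = psi_spec(), min_segments = 8) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  nfft <- round(spec$segment_s * fs)
  hop <- max(1L, round(nfft * (1 - spec$overlap)))
  if (length(x) < nfft) stop("series shorter than one segment", call. = FALSE)
  starts <- segment_starts(length(x), nfft, hop)
  if (length(starts) < min_segments) {
    stop(sprintf("only %d segments available (minimum %d)",
                 length(starts), min_segments), call. = FALSE)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / nfft)  # Hann
  bins <- seq_len(nfft %/% 2 + 1L)
  X <- seg_ffts(x, nfft, hop, bins, win)
  Y <- seg_ffts(y, nfft, hop, bins, win)
  Sxy <- rowSums(X * Conj(Y))
  den <- sqrt(rowSums(Mod(X)^2) * rowSums(Mod(Y)^2))
  C <- ifelse(den > 0, Sxy / den, 0i)
  structure(list(freqs = (bins - 1) * fs / nfft, C = C,
                 n_segments = length(starts), df = fs / nfft),
            class = "coherence")
}

#' Phase slope index at a centre frequency
#'
#' `PSI(f_i) = Im( sum_{f_j in [f_i - beta/2, f_i + beta/2]} C*(f_j) C(f_j + df) )`.
#' Positive values indicate that the first series of the coherence leads the
#' second (the cross-spectral phase difference increases with frequency).
#'
#' @param C a `"coherence"` object.
#' @param f_i centre frequency (Hz).
#' @param beta integration bandwidth (Hz).
#' @return real scalar.
#' @export
phase_slope_index <- function(C, f_i, beta = 5) {
  if (f_i - beta / 2 < min(C$freqs) - 1e-9) {
    stop("PSI band leaves the frequency grid", call. = FALSE)
  }
  idx <- which(C$freqs >= f_i - beta / 2 - 1e-9 & C$freqs <= f_i + beta / 2 + 1e-9)
  if (length(idx) < 2 || max(idx) + 1L > length(C$C)) {
    stop("PSI band leaves the frequency grid", call. = FALSE)
  }
  Im(sum(Conj(C$C[idx]) * C$C[idx + 1L]))
}

## Shared machinery for observed and surrogate CFD maps. The "x" side is the
## raw signal (or an external reference series); the "y" side is the
## amplitude envelope of the signal at each amplitude frequency. Surrogates
## circularly shift the envelope before segmentation; segment spectra at
## shifted positions come from a sliding (circular) windowed DFT computed
## with full-length FFTs, one per (envelope, frequency bin).
cfd_engine <- function(x, fs, phase_freqs, amp_freqs, spec, reference = NULL,
                       amp_halfwidth = default_amp_halfwidth(),
                       n_surrogates = 0, seed = 1L, min_frac = 0.1,
                       min_segments = 8) {
  if (!is.null(reference) && length(reference) != length(x)) {
    stop("reference length differs from signal", call. = FALSE)
  }
  if (n_surrogates > 0) {
    ## trim to a fast FFT length: the surrogate machinery runs full-length
    ## circular sliding DFTs of the envelope
    n_use <- prev_good_length(length(x))
    x <- x[seq_len(n_use)]
    if (!is.null(reference)) reference <- reference[seq_len(n_use)]
  }
  n <- length(x)
  xs <- reference %||% x
  nfft <- round(spec$segment_s * fs)
  hop <- max(1L, round(nfft * (1 - spec$overlap)))
  starts <- segment_starts(n, nfft, hop)
  if (length(starts) < min_segments) {
    stop(sprintf("only %d segments available (minimum %d)",
                 length(starts), min_segments), call. = FALSE)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / nfft)
  df <- fs / nfft
  fmax <- max(phase_freqs) + spec$beta / 2 + 2 * df
  bins <- seq_len(floor(fmax / df) + 2L)          # bin b -> freq (b-1)*df
  freqs <- (bins - 1) * df

  X <- seg_ffts(xs, nfft, hop, bins, win)
  Sxx <- rowSums(Mod(X)^2)

  if (n_surrogates > 0) {
    set.seed(seed)
    lo <- ceiling(min_frac * n); hi <- floor((1 - min_frac) * n)
    shifts <- sample(lo:hi, n_surrogates, replace = TRUE)
  } else shifts <- integer(0)

  psi_at <- function(Cf, f_i) {
    idx <- which(freqs >= f_i - spec$beta / 2 - 1e-9 &
                 freqs <= f_i + spec$beta / 2 + 1e-9)
    Im(sum(Conj(Cf[idx]) * Cf[idx + 1L]))
  }

  vals <- matrix(NA_real_, length(phase_freqs), length(amp_freqs))
  surr <- if (n_surrogates > 0) {
    array(NA_real_, c(length(phase_freqs), length(amp_freqs), n_surrogates))
  } else NULL

  beng <- band_engine(x, fs)
  envs <- lapply(amp_freqs, function(fa) {
    if (fa - amp_halfwidth >= fs / 2) return(NULL)
    as.numeric(extract_amplitude(x, fs, fa, amp_halfwidth, engine = beng))
  })

  for (j in seq_along(amp_freqs)) {
    env <- envs[[j]]
    if (is.null(env)) next
    Y <- seg_ffts(env, nfft, hop, bins, win)
    Sxy <- rowSums(X * Conj(Y))
    den <- sqrt(Sxx * rowSums(Mod(Y)^2))
    Cf <- ifelse(den > 0, Sxy / den, 0i)
    for (i in seq_along(phase_freqs)) vals[i, j] <- psi_at(Cf, phase_freqs[i])

    if (n_surrogates > 0) {
      ## sliding circular windowed DFT of the envelope at each band bin:
      ## S(p, b) = sum_t env[(p + t) mod n] win[t] exp(-2pi i (b-1) t / nfft)
      Ef <- fft(env)
      Sall <- matrix(0i, n, length(bins))
      for (b in seq_along(bins)) {
        g <- numeric(n)
        g[1:nfft] <- win * exp(-2i * pi * (bins[b] - 1) * seq(0, nfft - 1) / nfft)
        Sall[, b] <- fft(Ef * Conj(fft(g)), inverse = TRUE) / n
      }
      for (s in seq_len(n_surrogates)) {
        pos <- ((starts - 1L + shifts[s]) %% n) + 1L
        Ys <- t(Sall[pos, , drop = FALSE])
        Sxy_s <- rowSums(X * Conj(Ys))
        den_s <- sqrt(Sxx * rowSums(Mod(Ys)^2))
        Cs <- ifelse(den_s > 0, Sxy_s / den_s, 0i)
        for (i in seq_along(phase_freqs)) {
          surr[i, j, s] <- psi_at(Cs, phase_freqs[i])
        }
      }
    }
  }
  list(vals = vals, surr = surr, freqs = freqs)
}

#' Cross-frequency directionality map
#'
#' For every (phase frequency, amplitude frequency) cell, computes the phase
#' slope index between the raw signal (or an external reference series) and
#' the signal's amplitude envelope at the amplitude frequency, evaluated at
#' the phase frequency, then multiplies it elementwise by the CFC
#' comodulogram normalised by its maximum (values in `[0, 1]`). Positive CFD
#' means the slow phase leads the fast amplitude.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param phase_freqs,amp_freqs frequency grids (Hz).
#' @param spec a [psi_spec()].
#' @param reference optional external series used as the phase-providing side
#'   (e.g. the upstream drive), instead of the signal itself.
#' @param cfc optional precomputed CFC `comodulogram` on the same grids.
#' @param min_segments minimum number of Welch segments.
#' @return a `comodulogram` with signed CFD `values`; the normalised CFC
#'   mask is stored in `meta$cfc_mask`.
#' @export
cfd_map <- function(x, fs, phase_freqs = default_phase_freqs(),
                    amp_freqs = default_amp_freqs(), spec = psi_spec(),
                    reference = NULL, cfc = NULL,
                    amp_halfwidth = default_amp_halfwidth(), min_segments = 8) {
  eng <- cfd_engine(x, fs, phase_freqs, amp_freqs, spec, reference,
                    amp_halfwidth = amp_halfwidth, min_segments = min_segments)
  if (is.null(cfc)) {
    cfc <- cfc_comodulogram(x, fs, phase_freqs, amp_freqs,
                            amp_halfwidth = amp_halfwidth)
  }
  if (!identical(cfc$phase_freqs, phase_freqs) ||
      !identical(cfc$amp_freqs, amp_freqs)) {
    stop("CFC grids do not match the CFD grids", call. = FALSE)
  }
  m <- cfc$values / max(cfc$values, na.rm = TRUE)
  new_comodulogram(phase_freqs, amp_freqs, eng$vals * m,
                   meta = list(kind = "CFD", fs = fs, psi_spec = spec,
                               cfc_mask = m, external_reference = !is.null(reference)))
}

#' Average CFD over cells of high CFC
#'
#' Averages the CFD over comodulogram cells whose CFC exceeds the given
#' quantile of the CFC values, summarising the predominant directionality.
#'
#' @param cfd CFD `comodulogram`.
#' @param cfc CFC `comodulogram` on the same grids.
#' @param quantile CFC retention quantile (default 0.95).
#' @return scalar CFD_avg.
#' @export
cfd_avg <- function(cfd, cfc, quantile = 0.95) {
  if (!identical(cfd$phase_freqs, cfc$phase_freqs) ||
      !identical(cfd$amp_freqs, cfc$amp_freqs)) {
    stop("CFD and CFC grids differ", call. = FALSE)
  }
  thr <- stats::quantile(cfc$values, quantile, na.rm = TRUE, names = FALSE)
  keep <- is.finite(cfc$values) & cfc$values > thr & is.finite(cfd$values)
  if (!any(keep)) stop("no cells exceed the CFC quantile", call. = FALSE)
  mean(cfd$values[keep])
}

#' Two-tailed surrogate cluster significance of a CFD map
#'
#' Builds surrogate CFD maps by circularly shifting the amplitude envelope
#' relative to the phase-providing series, then runs the cluster correction
#' separately above the upper quantile and below the mirrored lower quantile,
#' returning the union mask.
#'
#' @inheritParams cfd_map
#' @param n_surrogates number of envelope-shift surrogates.
#' @param quantile upper significance quantile (lower tail uses `1 - quantile`).
#' @param seed integer seed.
#' @return the CFD `comodulogram` with `mask` set (TRUE where significant in
#'   either tail) and per-tail details in `meta$significance`.
#' @export
cfd_significance <- function(x, fs, phase_freqs = default_phase_freqs(),
                             amp_freqs = default_amp_freqs(),
                             spec = psi_spec(), reference = NULL, cfc = NULL,
                             amp_halfwidth = default_amp_halfwidth(),
                             n_surrogates = 200, quantile = 0.99, seed = 1L,
                             min_segments = 8) {
  eng <- cfd_engine(x, fs, phase_freqs, amp_freqs, spec, reference,
                    amp_halfwidth = amp_halfwidth,
                    n_surrogates = n_surrogates, seed = seed,
                    min_segments = min_segments)
  if (is.null(cfc)) {
    cfc <- cfc_comodulogram(x, fs, phase_freqs, amp_freqs,
                            amp_halfwidth = amp_halfwidth)
  }
  m <- cfc$values / max(cfc$values, na.rm = TRUE)
  obs <- new_comodulogram(phase_freqs, amp_freqs, eng$vals * m,
                          meta = list(kind = "CFD", fs = fs, psi_spec = spec,
                                      cfc_mask = m))
  surr <- lapply(seq_len(n_surrogates), function(s)
    new_comodulogram(phase_freqs, amp_freqs, eng$surr[, , s] * m,
                     meta = list(kind = "CFD surrogate")))
  up <- cluster_significance(obs, surr, quantile, tail = "upper")
  lo <- cluster_significance(obs, surr, quantile, tail = "lower")
  obs$mask <- up$mask | lo$mask
  obs$meta$significance <- list(upper = up, lower = lo)
  obs$meta$n_surrogates <- n_surrogates
  obs
}
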