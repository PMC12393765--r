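## Spike-to-rate conversion and kNN mutual information with lag scanning.

#' Convert a spike train to a continuous rate series
#'
#' Convolves spikes with either a causal exponentially decaying kernel
#' (peak 1 at the spike time, decaying with the given time constant; no mass
#' before the spike) or a Gaussian kernel. The exponential is the default:
#' its 5 ms decay approximates the decay of fast excitatory synaptic
#' currents, so the result resembles the drive seen by a downstream layer.
#'
#' @param spike_times_ms numeric vector of spike times (ms); a raster from
#'   several units can simply be pooled.
#' @param duration_ms series duration (ms).
#' @param dt_ms sampling step of the output series (ms).
#' @param kernel `"exponential"` or `"gaussian"`.
#' @param timescale_ms decay time constant (exponential) or sd (Gaussian), ms.
#' @return list of class `"rate_series"`: `values`, `dt_ms`, `kernel`,
#'   `timescale_ms`.
#' @export
spikes_to_rate <- function(spike_times_ms, duration_ms, dt_ms = 1,
                           kernel = c("exponential", "gaussian"),
                           timescale_ms = 5) {
  kernel <- match.arg(kernel)
  assert_positive(timescale_ms, "timescale_ms")
  n <- max(1L, round(duration_ms / dt_ms))
  st <- spike_times_ms[spike_times_ms >= 0 & spike_times_ms < duration_ms]
  counts <- tabulate(pmin(floor(st / dt_ms) + 1L, n), nbins = n)
  if (kernel == "exponential") {
    a <- exp(-dt_ms / timescale_ms)
    values <- as.numeric(stats::filter(counts, a, method = "recursive"))
  } else {
    half <- ceiling(5 * timescale_ms / dt_ms)
    ker <- exp(-((-half:half) * dt_ms)^2 / (2 * timescale_ms^2))
    values <- stats::convolve(counts, rev(ker), type = "open")[(half + 1):(half + n)]
    values[values < 0] <- 0
  }
  structure(list(values = values, dt_ms = dt_ms, kernel = kernel,
                 timescale_ms = timescale_ms), class = "rate_series")
}

#' Mutual information between two series (kNN estimate)
#'
#' Kraskov-style k-nearest-neighbour estimate of the mutual information (in
#' nats). A vanishing amount of noise is added to break ties (rate series
#' contain exact zeros), as is standard for this estimator; the estimate is
#' invariant under strictly monotone marginal transformations up to
#' estimator noise.
#'
#' @param x,y numeric series of equal length (>= 500 samples recommended).
#' @param k number of neighbours.
#' @param seed seed for the tie-breaking jitter.
#' @return non-negative scalar (small negative values from estimator noise
#'   are clamped at the reported value; no clamping is applied).
#' @export
mutual_information <- function(x, y, k = 3, seed = 1L) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input series", call. = FALSE)
  x <- (x - mean(x)) / sd(x)
  y <- (y - mean(y)) / sd(y)
  set.seed(seed)
  x <- x + 1e-9 * rnorm(length(x))
  y <- y + 1e-9 * rnorm(length(y))
  .ksg_mi_cpp(x, y, as.integer(k))
}

#' Mutual information as a function of output lag
#'
#' Shifts the output series relative to the input by each lag (positive lags
#' delay the output, accounting for integration delays in the network),
#' optionally subsamples to reduce autocorrelation bias, and computes the
#' kNN mutual information at every lag.
#'
#' @param input,output `rate_series` objects with identical `dt_ms`.
#' @param lags_ms lag grid (ms).
#' @param subsample_ms target resolution before MI estimation (ms).
#' @param k neighbours for the MI estimate.
#' @param seed jitter seed.
#' @return list of class `"protocol_result"`: `lags_ms`, `mi_curve`,
#'   `max_mi`, `max_lag_ms`.
#' @export
lagged_mi <- function(input, output, lags_ms = seq(-50, 50, by = 2),
                      subsample_ms = 5, k = 3, seed = 1L) {
  stopifnot(inherits(input, "rate_series"), inherits(output, "rate_series"),
            input$dt_ms == output$dt_ms)
  dt <- input$dt_ms
  n <- min(length(input$values), length(output$values))
  stride <- max(1L, round(subsample_ms / dt))
  mi <- vapply(lags_ms, function(lag) {
    L <- round(lag / dt)
    if (abs(L) >= n - 10) stop("lag exceeds series length", call. = FALSE)
    if (L >= 0) {
      xi <- input$values[1:(n - L)]; yo <- output$values[(1 + L):n]
    } else {
      xi <- input$values[(1 - L):n]; yo <- output$values[1:(n + L)]
    }
    idx <- seq(1L, length(xi), by = stride)
    mutual_information(xi[idx], yo[idx], k = k, seed = seed)
  }, numeric(1))
  best <- which.max(mi)
  structure(list(lags_ms = lags_ms, mi_curve = mi, max_mi = mi[best],
                 max_lag_ms = lags_ms[best]), class = "protocol_result")
}
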