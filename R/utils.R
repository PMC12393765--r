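#' @useDynLib thetagamma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif rexp quantile approx convolve sd cor
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible component seed from a global seed
#'
#' Every randomized component of an experiment draws its seed
#' deterministically from the global seed, a component name, and an optional
#' realization index, so that fixing the global seed fixes the whole
#' experiment while individual input streams (theta drive, background noise,
#' parallel pathway) can be held fixed or varied independently.
#'
#' @param seed integer global seed.
#' @param component character scalar naming the random stream.
#' @param index non-negative integer, e.g. a realization index.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, component, index = 0L) {
  stopifnot(is.character(component), length(component) == 1L)
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 2147483647
  x <- (as.numeric(seed) %% 2147483647) * 48271 + h * 16807 + as.numeric(index) * 69621
  as.integer(x %% 2147483646L + 1)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

odd_up <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n + 1L else n
}
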