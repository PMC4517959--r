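#' Convert a mean/dispersion pair to Beta shape parameters
#'
#' The Beta-Binomial distribution used throughout this package is
#' parameterized by the mean success probability `p` and a dispersion
#' parameter `phi`: the Binomial probability is drawn from a Beta
#' distribution with shapes `a = p / phi` and `b = (1 - p) / phi`. Larger
#' `phi` means stronger overdispersion; the intraclass correlation between
#' trials of one observation is `phi / (1 + phi)`.
#'
#' @param p mean success probability, strictly inside (0, 1).
#' @param phi dispersion parameter, strictly positive.
#' @return An object of class `bb_params`: list with positive shapes `a`
#'   and `b`, satisfying `a / (a + b) == p`.
#' @examples
#' mean_to_shapes(0.5, 0.5)   # Beta(1, 1): uniform mixing
#' @export
mean_to_shapes <- function(p, phi) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single probability strictly inside (0, 1)")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("'phi' must be a single positive number")
  structure(list(a = p / phi, b = (1 - p) / phi), class = "bb_params")
}

#' Beta-Binomial log probability mass function
#'
#' `log P(k | n, a, b) = log C(n,k) + log B(k+a, n-k+b) - log B(a, b)`,
#' evaluated through log-gamma so that shapes far below 1 (strong
#' overdispersion) do not underflow.
#'
#' @param k number of successes (vectorized).
#' @param n number of trials (vectorized, recycled against `k`).
#' @param params a `bb_params` object from [mean_to_shapes()], or a list
#'   with elements `a` and `b`.
#' @return log probabilities, same length as `k`.
#' @export
betabinom_logpmf <- function(k, n, params) {
  a <- params$a
  b <- params$b
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("shape parameters must be positive and finite")
  m <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), m)
  n <- rep_len(as.numeric(n), m)
  if (any(n < 0) || any(k < 0) || any(k > n))
    stop("'k' must satisfy 0 <= k <= n")
  bb_logpmf_cpp(k, n, rep_len(as.numeric(a), m), rep_len(as.numeric(b), m))
}

#' Sample from the Beta-Binomial distribution
#'
#' Two-stage draw: `q ~ Beta(p/phi, (1-p)/phi)`, then `Binomial(n, q)`.
#' `phi = 0` short-circuits to a plain Binomial draw (the weak-dispersion
#' limit). Uses the current R random number stream.
#'
#' @param n number of trials (vectorized).
#' @param p mean success probability (scalar or vector recycled to `n`).
#' @param phi dispersion parameter, `>= 0`.
#' @return integer vector of counts in `[0, n]`.
#' @export
betabinom_sample <- function(n, p, phi) {
  if (any(n < 0)) stop("'n' must be nonnegative")
  if (any(p <= 0) || any(p >= 1)) stop("'p' must be strictly inside (0, 1)")
  if (length(phi) != 1L || phi < 0) stop("'phi' must be a single value >= 0")
  m <- length(n)
  p <- rep_len(p, m)
  if (phi == 0) return(rbinom(m, n, p))
  q <- rbeta(m, p / phi, (1 - p) / phi)
  rbinom(m, n, q)
}

#' Mean and variance of the Beta-Binomial distribution
#'
#' mean `n p`; variance `n p (1-p) (1 + (n-1) rho)` with intraclass
#' correlation `rho = phi / (1 + phi)`.
#'
#' @inheritParams betabinom_sample
#' @return list with elements `mean` and `variance`.
#' @export
betabinom_moments <- function(n, p, phi) {
  if (any(n < 0)) stop("'n' must be nonnegative")
  if (any(p <= 0) || any(p >= 1)) stop("'p' must be strictly inside (0, 1)")
  if (any(phi < 0)) stop("'phi' must be >= 0")
  rho <- phi / (1 + phi)
  list(mean = n * p, variance = n * p * (1 - p) * (1 + (n - 1) * rho))
}
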