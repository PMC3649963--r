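# Exact one-sided tail probabilities, carried in log10 space so values far
# below double underflow (p < 1e-300) remain representable.

#' One-sided binomial tail probability P(X >= k)
#'
#' Exact survival value of `Binomial(n, p0)`, computed in log space.
#'
#' @param k Observed successes (vectorised).
#' @param n Number of trials.
#' @param p0 Success probability.
#' @param log10 Return log10 of the p-value (default `FALSE`).
#' @return P(X >= k), or its log10.
#' @examples
#' binomial_sf(7, 10, 0.5)            # 176/1024
#' binomial_sf(1237, 2337, 60.5/2337, log10 = TRUE)
#' @export
binomial_sf <- function(k, n, p0, log10 = FALSE) {
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  if (any(n < 0)) stop("n must be >= 0")
  lp <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
  if (log10) lp else 10^lp
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Exact tail of `Hypergeometric(N, K, n)`: `k` successes when drawing `n`
#' from a population of `N` containing `K` successes.
#'
#' @param k Observed successes in the draw (vectorised).
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param log10 Return log10 of the p-value.
#' @return P(X >= k), or its log10.
#' @examples
#' hypergeom_sf(5, 10, 5, 5)   # 1/252
#' @export
hypergeom_sf <- function(k, N, K, n, log10 = FALSE) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k < 0)) stop("k must be >= 0")
  if (any(k > pmin(K, n) + 1)) stop("k exceeds the achievable maximum")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE) / log(10)
  if (log10) lp else 10^lp
}

#' Hypergeometric point probability P(X = k)
#'
#' @inheritParams hypergeom_sf
#' @return P(X = k), or its log10.
#' @export
hypergeom_point <- function(k, N, K, n, log10 = FALSE) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  lp <- stats::dhyper(k, K, N - K, n, log = TRUE) / log(10)
  if (log10) lp else 10^lp
}
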