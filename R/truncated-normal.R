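#' Moments of a doubly truncated normal distribution
#'
#' Returns the mean and variance of \eqn{N(\mu, \sigma^2)} truncated to
#' \eqn{[a, b]}, together with the standardized moment factors
#' \eqn{\beta_1} and \eqn{\beta_2} in the convention of Johnson, Kotz and
#' Balakrishnan: with \eqn{g_a = (a-\mu)/\sigma}, \eqn{g_b = (b-\mu)/\sigma}
#' and \eqn{Z = \Phi(g_b) - \Phi(g_a)},
#' \deqn{\beta_1 = \frac{\phi(g_b) - \phi(g_a)}{Z}, \qquad
#'       \beta_2 = \frac{g_b\phi(g_b) - g_a\phi(g_a)}{Z} + \beta_1^2,}
#' so that \eqn{-\beta_1} and \eqn{1 - \beta_2} are the mean and variance of
#' the standard truncated normal on \eqn{[g_a, g_b]}.
#'
#' @param mu Location of the untruncated normal.
#' @param sigma2 Variance of the untruncated normal (positive).
#' @param a,b Truncation endpoints, \code{a < b}; either may be infinite.
#'
#' @return A list with components \code{beta1}, \code{beta2}, \code{mean}
#'   (\eqn{\mu - \sigma\beta_1}) and \code{variance}
#'   (\eqn{\sigma^2(1 - \beta_2)}).
#'
#' @examples
#' tnorm_moments(0, 1, 0, Inf)  # half normal: mean sqrt(2/pi)
#' @export
tnorm_moments <- function(mu, sigma2, a, b) {
  stopifnot(sigma2 > 0)
  check_interval(a, b)
  s <- sqrt(sigma2)
  g_a <- (a - mu) / s
  g_b <- (b - mu) / s
  z <- pnorm_diff(g_a, g_b)
  if (z < 1e-300) {
    stop("truncation region [", a, ", ", b, "] carries essentially no mass")
  }
  beta1 <- (dnorm(g_b) - dnorm(g_a)) / z
  beta2 <- (xphi(g_b) - xphi(g_a)) / z + beta1^2
  list(
    beta1 = beta1, beta2 = beta2,
    mean = mu - s * beta1,
    variance = sigma2 * (1 - beta2)
  )
}

#' Sample from a doubly truncated normal distribution
#'
#' Draws from \eqn{N(\mu, \sigma^2)} conditioned on \eqn{[a, b]} using the
#' tail-robust rejection sampler of the truncnorm package, under an
#' explicit seed.
#'
#' @param n Number of draws.
#' @param mu,sigma2,a,b As in [tnorm_moments()].
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#'
#' @return Numeric vector of \code{n} draws supported on \eqn{[a, b]}.
#' @export
tnorm_sample <- function(n, mu, sigma2, a, b, seed = NULL) {
  stopifnot(n >= 1, sigma2 > 0)
  check_interval(a, b)
  s <- sqrt(sigma2)
  if (pnorm_diff((a - mu) / s, (b - mu) / s) < 1e-300) {
    stop("truncation region [", a, ", ", b, "] carries essentially no mass")
  }
  with_seed(seed, truncnorm::rtruncnorm(n, a = a, b = b, mean = mu, sd = s))
}
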