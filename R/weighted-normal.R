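#' Weighted (interval-screened) normal parameters
#'
#' The weighted normal distribution \eqn{WN_{(a,b)}(m, \Omega)} is the law
#' of the second coordinate of a bivariate normal \eqn{N_2(m, \Omega)}
#' conditioned on its first (screening) coordinate falling in
#' \eqn{[a, b]}.  This constructor validates the parameters and
#' precomputes the derived quantities used by the density, sampler and
#' moment routines.
#'
#' A zero screening variance (\code{Omega[1,1] == 0}, which arises from
#' [wn_prior()] at \code{delta = 0}) or a doubly infinite interval makes
#' the screening vacuous and the distribution collapses to
#' \eqn{N(m_2, \Omega_{22})}.
#'
#' @param m Numeric 2-vector: locations of the screening and outcome
#'   coordinates.
#' @param Omega Symmetric 2x2 covariance matrix with positive outcome
#'   variance and nonnegative definite structure.
#' @param a,b Screening interval endpoints, \code{a < b}; either may be
#'   infinite.
#'
#' @return An object of class \code{"wn_params"}.
#' @seealso [wn_prior()] for the prior parameterization driven by
#'   \eqn{(\mu, \sigma^2, \delta)}.
#' @export
wn_params <- function(m, Omega, a, b) {
  stopifnot(is.numeric(m), length(m) == 2L, all(is.finite(m)))
  stopifnot(is.matrix(Omega), all(dim(Omega) == 2L), all(is.finite(Omega)))
  check_interval(a, b)
  if (abs(Omega[1, 2] - Omega[2, 1]) > 1e-10 * (1 + max(abs(Omega)))) {
    stop("Omega must be symmetric")
  }
  o11 <- Omega[1, 1]; o12 <- (Omega[1, 2] + Omega[2, 1]) / 2; o22 <- Omega[2, 2]
  if (o22 <= 0) stop("outcome variance Omega[2,2] must be positive")
  if (o11 < 0) stop("screening variance Omega[1,1] must be nonnegative")
  screened <- o11 > 0 && o12 != 0 && !(a == -Inf && b == Inf)
  p <- list(
    m = as.numeric(m), Omega = matrix(c(o11, o12, o12, o22), 2L),
    a = a, b = b, screened = screened
  )
  if (o11 > 0) {
    det <- o11 * o22 - o12^2
    if (det < -1e-10 * o11 * o22) stop("Omega must be nonnegative definite")
    s1 <- sqrt(o11)
    p$s1 <- s1
    p$g_a <- (a - m[1]) / s1          # standardized screening endpoints
    p$g_b <- (b - m[1]) / s1
    p$kappa <- o12 / s1               # Cov(X1, X2) / sd(X1)
    p$c2sq <- max(o22 - o12^2 / o11, 0)  # residual outcome variance
    p$slope <- o12 / o22              # regression of X1 on X2
    p$sc <- sqrt(max(o11 - o12^2 / o22, 0))
    p$logZ <- log_pnorm_diff(p$g_a, p$g_b)
    if (screened && p$logZ < log(1e-300)) {
      stop("screening interval carries essentially no mass")
    }
  }
  class(p) <- "wn_params"
  p
}

#' @export
print.wn_params <- function(x, ...) {
  cat("Weighted (interval-screened) normal parameters\n")
  cat("  m     =", format(x$m), "\n")
  cat("  Omega =", format(x$Omega[1, ]), "/", format(x$Omega[2, ]), "\n")
  cat("  screening interval [", x$a, ",", x$b, "]",
      if (!x$screened) "(vacuous)", "\n")
  invisible(x)
}

#' Screened-normal prior parameters from (mu, sigma2, delta)
#'
#' Builds the weighted-normal parameterization of the two-stage prior:
#' locations \eqn{(\mu, \mu)} and covariance
#' \eqn{\Sigma = \sigma^2 [\delta, \delta; \delta, 1]}, so the screening
#' coordinate has variance \eqn{\delta\sigma^2} and correlation
#' \eqn{\sqrt\delta} with the outcome.  \code{delta = 0} gives the
#' unscreened \eqn{N(\mu, \sigma^2)} prior exactly; values of
#' \code{delta} at or above \code{1 - 1e-6} are clipped with a warning
#' because the covariance becomes singular at \eqn{\delta = 1}.
#'
#' @param mu Prior mean.
#' @param sigma2 Total prior variance (positive).
#' @param delta Screening proportion in \eqn{[0, 1)}.
#' @param a,b Constraint interval endpoints.
#'
#' @return A \code{"wn_params"} object.
#' @export
wn_prior <- function(mu, sigma2, delta, a, b) {
  stopifnot(sigma2 > 0, delta >= 0, delta <= 1)
  if (delta >= 1 - 1e-6) {
    warning("delta clipped to 1 - 1e-6; the screening covariance is singular at delta = 1")
    delta <- 1 - 1e-6
  }
  Omega <- sigma2 * matrix(c(delta, delta, delta, 1), 2L)
  wn_params(c(mu, mu), Omega, a, b)
}

# log of the screening weight Phi(u_b(theta)) - Phi(u_a(theta)), i.e. the
# conditional probability that the screening coordinate lands in [a, b]
# given the outcome value theta.  Vectorized over theta.
wn_log_weight <- function(theta, p) {
  if (!p$screened) return(rep(0, length(theta)))
  cm <- p$m[1] + p$slope * (theta - p$m[2])
  log_pnorm_diff((p$a - cm) / p$sc, (p$b - cm) / p$sc)
}

#' Weighted-normal density
#'
#' Density of the screened (weighted) normal distribution:
#' \deqn{f(\theta) = \phi(\theta; m_2, \Omega_{22})\,
#'   \frac{\Phi(u_b(\theta)) - \Phi(u_a(\theta))}{P(a \le X_1 \le b)},}
#' where \eqn{u_a, u_b} standardize the conditional law of the screening
#' coordinate given the outcome.  Both \eqn{\Phi}-differences are
#' evaluated through complementary forms in the tails.
#'
#' @param theta Numeric vector of evaluation points.
#' @param p A \code{"wn_params"} object.
#' @param log Return the log density?
#'
#' @return Numeric vector of (log) density values.
#' @export
dwn <- function(theta, p, log = FALSE) {
  stopifnot(inherits(p, "wn_params"))
  ld <- dnorm(theta, p$m[2], sqrt(p$Omega[2, 2]), log = TRUE)
  if (p$screened) ld <- ld + wn_log_weight(theta, p) - p$logZ
  if (log) ld else exp(ld)
}

#' Sample from the weighted normal distribution
#'
#' Uses the stochastic representation
#' \eqn{\theta = m_2 + \kappa Z_{tr} + \sqrt{\Omega_{22} -
#' \Omega_{12}^2/\Omega_{11}}\, Z}, where \eqn{Z_{tr}} is a standard
#' normal truncated to the standardized screening interval,
#' \eqn{Z} an independent standard normal and
#' \eqn{\kappa = \Omega_{12}/\sqrt{\Omega_{11}}}.  In the prior
#' parameterization of [wn_prior()] this is exactly
#' \eqn{\mu + \sigma\sqrt\delta\, Z_{tr} + \sigma\sqrt{1-\delta}\, Z}.
#'
#' @param n Number of draws.
#' @param p A \code{"wn_params"} object.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of \code{n} draws.
#' @export
rwn <- function(n, p, seed = NULL) {
  stopifnot(inherits(p, "wn_params"), n >= 1)
  with_seed(seed, {
    if (!p$screened) {
      rnorm(n, p$m[2], sqrt(p$Omega[2, 2]))
    } else {
      zt <- truncnorm::rtruncnorm(n, a = p$g_a, b = p$g_b)
      p$m[2] + p$kappa * zt + sqrt(p$c2sq) * rnorm(n)
    }
  })
}

#' Mean and variance of the weighted normal distribution
#'
#' Closed-form moments: with \eqn{\beta_1, \beta_2} the truncated-normal
#' moment factors of the standardized screening coordinate and
#' \eqn{\kappa = \Omega_{12}/\sqrt{\Omega_{11}}},
#' \deqn{E[\theta] = m_2 - \beta_1\kappa, \qquad
#'       Var(\theta) = \Omega_{22} - \beta_2\kappa^2.}
#'
#' @param p A \code{"wn_params"} object.
#' @return List with \code{mean}, \code{variance}, \code{beta1},
#'   \code{beta2} and \code{kappa} (all zero-screening when vacuous).
#' @export
wn_moments <- function(p) {
  stopifnot(inherits(p, "wn_params"))
  if (!p$screened) {
    return(list(mean = p$m[2], variance = p$Omega[2, 2],
                beta1 = 0, beta2 = 0, kappa = 0))
  }
  tm <- tnorm_moments(0, 1, p$g_a, p$g_b)
  list(
    mean = p$m[2] - tm$beta1 * p$kappa,
    variance = p$Omega[2, 2] - tm$beta2 * p$kappa^2,
    beta1 = tm$beta1, beta2 = tm$beta2, kappa = p$kappa
  )
}

#' Rejection-sampling oracle for the weighted normal distribution
#'
#' Draws \eqn{(X_1, X_2)} from the underlying bivariate normal and keeps
#' \eqn{X_2} whenever \eqn{X_1 \in [a, b]}, until \code{n} draws are
#' accepted.  This realizes the defining representation
#' \eqn{\theta \overset{d}{=} [X_2 \mid a \le X_1 \le b]} directly and is
#' intended as an independent check on [rwn()] and [wn_moments()].
#'
#' @param n Number of accepted draws required.
#' @param p A \code{"wn_params"} object.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of \code{n} draws with attribute
#'   \code{"acceptance_rate"} (the empirical acceptance proportion).
#' @export
rwn_reject <- function(n, p, seed = NULL) {
  stopifnot(inherits(p, "wn_params"), n >= 1)
  if (p$screened && exp(p$logZ) < 1e-5) {
    stop("screening acceptance probability below 1e-5; use rwn() instead")
  }
  with_seed(seed, {
    if (!p$screened) {
      out <- rnorm(n, p$m[2], sqrt(p$Omega[2, 2]))
      attr(out, "acceptance_rate") <- 1
      return(out)
    }
    rate <- exp(p$logZ)
    kept <- numeric(0)
    proposed <- 0
    accepted <- 0
    csd <- sqrt(p$c2sq)
    while (accepted < n) {
      m <- ceiling(min(max((n - accepted) / rate * 1.2, 1e4), 5e6))
      x1 <- rnorm(m, p$m[1], p$s1)
      ok <- x1 >= p$a & x1 <= p$b
      x2 <- p$m[2] + (p$kappa / p$s1) * (x1[ok] - p$m[1]) + csd * rnorm(sum(ok))
      kept <- c(kept, x2)
      proposed <- proposed + m
      accepted <- accepted + sum(ok)
    }
    out <- kept[seq_len(n)]
    attr(out, "acceptance_rate") <- accepted / proposed
    out
  })
}
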