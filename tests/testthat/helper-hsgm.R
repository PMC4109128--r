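# Shared test oracles. These deliberately avoid the package's own code
# paths: the MC oracles draw from the defining representations directly,
# and the quadrature oracles integrate densities numerically.

# Conditional-probability MC estimate of alpha = P(X2 in [a,b] | X1 in [a,b])
# for (X1, X2) bivariate normal with means mu, variances delta*sigma2 and
# sigma2, covariance delta*sigma2. Returns the estimate and its SE.
mc_alpha <- function(mu, sigma2, delta, a, b, n = 1e7, seed = 1,
                     chunk = 2e6) {
  set.seed(seed)
  s <- sqrt(sigma2)
  rho <- sqrt(delta)
  hits <- 0
  total <- 0
  remaining <- n
  while (remaining > 0) {
    m <- min(chunk, remaining)
    z1 <- rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
    x1 <- mu + s * sqrt(delta) * z1
    x2 <- mu + s * z2
    sel <- x1 >= a & x1 <= b
    hits <- hits + sum(x2[sel] >= a & x2[sel] <= b)
    total <- total + sum(sel)
    remaining <- remaining - m
  }
  est <- hits / total
  list(alpha = est, se = sqrt(est * (1 - est) / total))
}

# -integral of p log p by adaptive quadrature for a density function f.
quad_entropy <- function(f, lower = -Inf, upper = Inf) {
  integrand <- function(t) {
    d <- f(t)
    ifelse(d > 0, -d * log(d), 0)
  }
  integrate(integrand, lower, upper, rel.tol = 1e-11,
            abs.tol = 1e-12)$value
}

# Posterior oracle for the delta = 0 (plain normal prior) subcase:
# integrates theta out of the normal--inverse-gamma semi-conjugate
# posterior on a quadrature grid. Returns exact posterior means/sds of
# theta and the posterior mean of tau2.
nig_posterior_oracle <- function(y, mu, sigma2, c, d) {
  n <- length(y)
  shape <- c + n / 2
  lpt <- function(t) {
    dnorm(t, mu, sqrt(sigma2), log = TRUE) -
      shape * log(d + 0.5 * sapply(t, function(tt) sum((y - tt)^2)))
  }
  mx <- lpt(mean(y))
  z <- integrate(function(t) exp(lpt(t) - mx), -Inf, Inf, rel.tol = 1e-10)$value
  em <- integrate(function(t) t * exp(lpt(t) - mx), -Inf, Inf,
                  rel.tol = 1e-10)$value / z
  e2 <- integrate(function(t) t^2 * exp(lpt(t) - mx), -Inf, Inf,
                  rel.tol = 1e-10)$value / z
  et2 <- integrate(function(t) {
    rate <- d + 0.5 * sapply(t, function(tt) sum((y - tt)^2))
    rate / (shape - 1) * exp(lpt(t) - mx)
  }, -Inf, Inf, rel.tol = 1e-10)$value / z
  list(theta_mean = em, theta_sd = sqrt(e2 - em^2), tau2_mean = et2)
}
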