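#' Standardized bivariate-normal rectangle probability
#'
#' \eqn{P(l_1 \le X_1 \le u_1,\ l_2 \le X_2 \le u_2)} for standard normal
#' margins with correlation \code{rho}, computed by inclusion-exclusion
#' over four evaluations of the bivariate normal CDF (Genz's TVPACK
#' routine, absolute accuracy around \code{1e-14}).  Infinite endpoints
#' reduce to univariate probabilities.
#'
#' @param lower1,upper1 Bounds on the first coordinate (infinite allowed).
#' @param lower2,upper2 Bounds on the second coordinate.
#' @param rho Correlation, strictly inside \eqn{(-1, 1)}.
#'
#' @return A probability in \eqn{[0, 1]}.
#' @export
bvn_rect_prob <- function(lower1, upper1, lower2, upper2, rho) {
  check_interval(lower1, upper1)
  check_interval(lower2, upper2)
  stopifnot(is.numeric(rho), length(rho) == 1L)
  if (abs(rho) >= 1) stop("|rho| must be strictly less than 1")
  if (rho == 0) {
    return(pnorm_diff(lower1, upper1) * pnorm_diff(lower2, upper2))
  }
  F2 <- function(x, y) {
    if (x == -Inf || y == -Inf) return(0)
    if (x == Inf && y == Inf) return(1)
    if (x == Inf) return(pnorm(y))
    if (y == Inf) return(pnorm(x))
    as.numeric(mvtnorm::pmvnorm(
      upper = c(x, y), corr = matrix(c(1, rho, rho, 1), 2L),
      algorithm = mvtnorm::TVPACK()
    ))
  }
  p <- F2(upper1, upper2) - F2(lower1, upper2) -
    F2(upper1, lower2) + F2(lower1, lower2)
  min(max(p, 0), 1)
}

#' Objective degree of uncertainty about the interval constraint
#'
#' For the two-stage prior with total variance \eqn{\sigma^2} and
#' screening proportion \eqn{\delta}, the prior probability that
#' \eqn{\theta} actually falls in \eqn{[a, b]} is the conditional
#' rectangle probability
#' \deqn{\alpha(\delta) = \frac{\bar\Phi_2((a,b); \mu, \Sigma)}
#'   {\Phi(v^*(b)) - \Phi(v^*(a))},}
#' where \eqn{\Sigma = \sigma^2[\delta, \delta; \delta, 1]}, the
#' standardized coordinates have correlation \eqn{\sqrt\delta} and
#' \eqn{v^*(x) = (x - \mu)/(\sigma\sqrt\delta)}.  The degree of
#' uncertainty carried by the prior is \eqn{(1 - \alpha) \times 100\%}.
#'
#' At \code{delta = 0} the screening coordinate is degenerate at
#' \eqn{\mu}: \eqn{\alpha} is defined as \eqn{\Phi(v(b)) - \Phi(v(a))}
#' when \eqn{\mu \in [a, b]} (the continuity limit) and 0 otherwise.
#'
#' @param mu Prior mean.
#' @param sigma2 Prior variance (positive).
#' @param delta Screening proportion in \eqn{[0, 1)}.
#' @param a,b Constraint interval endpoints; finite screening mass is
#'   required when \code{delta > 0}.
#'
#' @return An object of class \code{"uncertainty_report"}: a list with
#'   \code{alpha}, \code{degree_percent} (\eqn{(1-\alpha)\times 100}),
#'   \code{delta}, \code{mu}, \code{sigma2}, \code{a}, \code{b},
#'   \code{sigma0_2} (\eqn{(1-\delta)\sigma^2}) and \code{sigma1_2}
#'   (\eqn{\delta\sigma^2}).
#' @export
alpha_of_delta <- function(mu, sigma2, delta, a, b) {
  stopifnot(sigma2 > 0, delta >= 0, delta < 1)
  check_interval(a, b)
  s <- sqrt(sigma2)
  v_a <- (a - mu) / s
  v_b <- (b - mu) / s
  if (delta == 0) {
    alpha <- if (mu >= a && mu <= b) pnorm_diff(v_a, v_b) else 0
  } else {
    sd1 <- s * sqrt(delta)
    vs_a <- (a - mu) / sd1
    vs_b <- (b - mu) / sd1
    z <- pnorm_diff(vs_a, vs_b)
    if (z < 1e-300) stop("screening interval carries essentially no mass")
    num <- bvn_rect_prob(vs_a, vs_b, v_a, v_b, sqrt(delta))
    alpha <- min(max(num / z, 0), 1)
  }
  structure(list(alpha = alpha, degree_percent = (1 - alpha) * 100,
                 delta = delta, mu = mu, sigma2 = sigma2, a = a, b = b,
                 sigma0_2 = (1 - delta) * sigma2,
                 sigma1_2 = delta * sigma2),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("Interval constraint [%g, %g], delta = %g:\n", x$a, x$b, x$delta))
  cat(sprintf("  alpha = %.6f  => degree of uncertainty (1 - alpha) = %.3f%%\n",
              x$alpha, x$degree_percent))
  cat(sprintf("  variance split: sigma0^2 = %.6g (free), sigma1^2 = %.6g (constrained)\n",
              x$sigma0_2, x$sigma1_2))
  invisible(x)
}

#' Screening proportion matching a prescribed degree of uncertainty
#'
#' Inverts the monotone map \eqn{\delta \mapsto (1-\alpha(\delta)) \times
#' 100\%} by bisection, answering the elicitation question: which split
#' of the prior variance into \eqn{\sigma_0^2 = (1-\delta)\sigma^2} and
#' \eqn{\sigma_1^2 = \delta\sigma^2} encodes a stated degree of
#' uncertainty about the interval constraint?
#'
#' @param target_degree_percent Desired degree of uncertainty, strictly
#'   inside the attainable range (close to 0\% as \eqn{\delta \to 1}, up
#'   to the \eqn{\delta \to 0} limit).
#' @param mu,sigma2,a,b Prior mean, variance and constraint interval.
#' @param tol Tolerance on the achieved degree, in percentage points.
#'
#' @return A list with \code{delta}, the implied \code{sigma0_2} and
#'   \code{sigma1_2}, and the full \code{report} from [alpha_of_delta()]
#'   at the returned \code{delta}.
#' @export
delta_for_uncertainty <- function(target_degree_percent, mu, sigma2, a, b,
                                  tol = 1e-6) {
  stopifnot(target_degree_percent > 0, target_degree_percent < 100)
  check_interval(a, b)
  degree <- function(d) alpha_of_delta(mu, sigma2, d, a, b)$degree_percent
  lo <- 1e-10
  hi <- 1 - 1e-10
  d_lo <- degree(lo)
  d_hi <- degree(hi)
  if (d_lo <= d_hi) stop("degree of uncertainty is not decreasing in delta for these inputs")
  if (target_degree_percent >= d_lo || target_degree_percent <= d_hi) {
    stop(sprintf(
      "target %.6f%% outside the attainable range (%.6f%%, %.6f%%)",
      target_degree_percent, d_hi, d_lo))
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    d_mid <- degree(mid)
    if (abs(d_mid - target_degree_percent) < tol && (hi - lo) < 1e-9) break
    if (d_mid > target_degree_percent) lo <- mid else hi <- mid
  }
  delta <- (lo + hi) / 2
  list(delta = delta,
       sigma0_2 = (1 - delta) * sigma2,
       sigma1_2 = delta * sigma2,
       report = alpha_of_delta(mu, sigma2, delta, a, b))
}

#' Uncertainty-degree curves over a grid
#'
#' Tabulates \eqn{\alpha(\delta)} and the degree of uncertainty
#' \eqn{(1-\alpha)\times 100\%} over a grid of prior variances and
#' screening proportions, one row per combination.
#'
#' @param mu Prior mean.
#' @param sigma2 Vector of prior variances.
#' @param a,b Constraint interval endpoints.
#' @param delta_grid Values in \eqn{[0, 1)}.
#'
#' @return A data frame with columns \code{sigma2}, \code{delta},
#'   \code{alpha}, \code{degree_percent}.
#' @export
uncertainty_curve <- function(mu, sigma2, a, b, delta_grid) {
  grid <- expand.grid(delta = delta_grid, sigma2 = sigma2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- alpha_of_delta(mu, grid$sigma2[i], grid$delta[i], a, b)
    data.frame(sigma2 = r$sigma2, delta = r$delta,
               alpha = r$alpha, degree_percent = r$degree_percent)
  })
  do.call(rbind, rows)
}
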