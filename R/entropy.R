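#' Specify one of the three maximum-entropy priors
#'
#' The three priors that maximize differential entropy for a normal mean
#' given a prior mean \eqn{\mu}, prior variance \eqn{\sigma^2} and an
#' interval statement about \eqn{\theta}:
#' \describe{
#'   \item{\code{"unconstrained"}}{no interval information:
#'     \eqn{N(\mu, \sigma^2)}.}
#'   \item{\code{"certain"}}{\eqn{\theta \in [a,b]} with certainty:
#'     the doubly truncated normal.}
#'   \item{\code{"uncertain"}}{\eqn{\theta \in [a,b]} held with
#'     uncertainty: the weighted (screened) normal of [wn_prior()] with
#'     screening proportion \code{delta}.}
#' }
#'
#' @param mu Prior mean.
#' @param sigma2 Prior variance (positive).
#' @param case One of \code{"unconstrained"}, \code{"certain"},
#'   \code{"uncertain"}.
#' @param a,b Interval endpoints (ignored when unconstrained).
#' @param delta Screening proportion in \eqn{[0, 1)}; used only for the
#'   uncertain case.
#'
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(mu, sigma2, case = c("unconstrained", "certain", "uncertain"),
                       a = -Inf, b = Inf, delta = NULL) {
  case <- match.arg(case)
  stopifnot(is.numeric(mu), length(mu) == 1L, sigma2 > 0)
  if (case != "unconstrained") check_interval(a, b)
  if (case == "certain") {
    s <- sqrt(sigma2)
    if (pnorm_diff((a - mu) / s, (b - mu) / s) < 1e-300) {
      stop("the certain-constraint prior needs positive mass on [a, b]")
    }
  }
  if (case == "uncertain") {
    if (is.null(delta)) stop("the uncertain case requires delta")
    stopifnot(delta >= 0, delta < 1)
  } else {
    delta <- NULL
  }
  structure(list(mu = mu, sigma2 = sigma2, a = a, b = b,
                 case = case, delta = delta),
            class = "prior_spec")
}

#' Density of a maximum-entropy prior
#'
#' @param theta Numeric vector of evaluation points.
#' @param spec A [prior_spec()] object.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values; the certain case is
#'   zero outside \eqn{[a, b]}.
#' @export
prior_density <- function(theta, spec, log = FALSE) {
  stopifnot(inherits(spec, "prior_spec"))
  s <- sqrt(spec$sigma2)
  ld <- switch(spec$case,
    unconstrained = dnorm(theta, spec$mu, s, log = TRUE),
    certain = {
      z <- log_pnorm_diff((spec$a - spec$mu) / s, (spec$b - spec$mu) / s)
      ifelse(theta >= spec$a & theta <= spec$b,
             dnorm(theta, spec$mu, s, log = TRUE) - z, -Inf)
    },
    uncertain = dwn(theta, wn_prior(spec$mu, spec$sigma2, spec$delta,
                                    spec$a, spec$b), log = TRUE)
  )
  if (log) ld else exp(ld)
}

entropy_estimate <- function(value, mc_se = 0, n_draws = 0, seed = NULL,
                             method = c("closed_form", "monte_carlo")) {
  structure(list(value = value, mc_se = mc_se, n_draws = n_draws,
                 seed = seed, method = match.arg(method)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Differential entropy: %.6f nats", x$value))
  if (x$n_draws > 0) {
    cat(sprintf("  (MC, n = %d, se = %.2g)", x$n_draws, x$mc_se))
  } else {
    cat("  (closed form)")
  }
  cat("\n")
  invisible(x)
}

#' Closed-form differential entropy of the unconstrained or certain prior
#'
#' For the unconstrained normal,
#' \eqn{\frac12(1 + \ln 2\pi + \ln\sigma^2)}; for the doubly truncated
#' normal on \eqn{[a,b]} with \eqn{v(x) = (x-\mu)/\sigma} and
#' \eqn{Z = \Phi(v(b)) - \Phi(v(a))},
#' \deqn{\tfrac12\Big(1 + \ln 2\pi\sigma^2 +
#'   \frac{v(a)\phi(v(a)) - v(b)\phi(v(b))}{Z}\Big) + \ln Z.}
#'
#' @param spec A [prior_spec()] with case \code{"unconstrained"} or
#'   \code{"certain"}; the uncertain case has no closed form (use
#'   [entropy_mc()]).
#' @return An \code{"entropy_estimate"} with \code{mc_se = 0}.
#' @export
entropy_closed_form <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (spec$case == "uncertain") {
    stop("the uncertain-case entropy has no closed form; use entropy_mc()")
  }
  if (spec$case == "unconstrained") {
    return(entropy_estimate(0.5 * (1 + log(2 * pi) + log(spec$sigma2))))
  }
  s <- sqrt(spec$sigma2)
  v_a <- (spec$a - spec$mu) / s
  v_b <- (spec$b - spec$mu) / s
  z <- pnorm_diff(v_a, v_b)
  val <- 0.5 * (1 + log(2 * pi * spec$sigma2) + (xphi(v_a) - xphi(v_b)) / z) +
    log(z)
  entropy_estimate(val)
}

#' Monte-Carlo differential entropy of the uncertain (screened) prior
#'
#' The screened-normal entropy splits into closed terms plus the expected
#' log screening weight,
#' \deqn{\tfrac12\Big\{1 + \ln 2\pi\sigma^2 + \delta\,
#'   \frac{v^*(a)\phi(v^*(a)) - v^*(b)\phi(v^*(b))}{Z^*}\Big\} + \ln Z^*
#'   - E[\ln W(\theta)],}
#' with \eqn{v^*(x) = (x-\mu)/(\sigma\sqrt\delta)},
#' \eqn{Z^* = \Phi(v^*(b)) - \Phi(v^*(a))} and \eqn{W(\theta)} the
#' conditional screening probability given \eqn{\theta}.  The expectation
#' is estimated by averaging \eqn{\ln W} over draws from the prior itself
#' (via its stochastic representation); its Monte-Carlo standard error is
#' reported.  At \code{delta = 0} the prior is exactly normal and the
#' closed form is returned with \code{mc_se = 0}.
#'
#' @param spec A [prior_spec()] with case \code{"uncertain"}.
#' @param n_draws Number of Monte-Carlo draws (at least 1000).
#' @param seed Optional integer seed.
#' @return An \code{"entropy_estimate"}.
#' @export
entropy_mc <- function(spec, n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), spec$case == "uncertain",
            n_draws >= 1e3)
  if (spec$delta < 1e-12) {
    return(entropy_estimate(0.5 * (1 + log(2 * pi) + log(spec$sigma2))))
  }
  p <- wn_prior(spec$mu, spec$sigma2, spec$delta, spec$a, spec$b)
  delta <- p$Omega[1, 1] / p$Omega[2, 2]  # after any clipping
  z <- exp(p$logZ)
  closed <- 0.5 * (1 + log(2 * pi * spec$sigma2) +
                     delta * (xphi(p$g_a) - xphi(p$g_b)) / z) + p$logZ
  theta <- rwn(n_draws, p, seed = seed)
  lw <- wn_log_weight(theta, p)
  entropy_estimate(closed - mean(lw), sd(lw) / sqrt(n_draws),
                   n_draws = n_draws, seed = seed, method = "monte_carlo")
}

#' Entropy-gap curves between the uncertain and certain priors
#'
#' Tabulates, over a grid of prior variances and screening proportions,
#' the entropies of the three maximum-entropy priors and the gap
#' \code{diff_ent = Ent(uncertain) - Ent(certain)}, which quantifies the
#' extra prior uncertainty retained by screening softly instead of
#' truncating.
#'
#' @param mu Prior mean.
#' @param sigma2 Vector of prior variances.
#' @param a,b Interval endpoints.
#' @param delta_grid Strictly increasing values in \eqn{(0, 1)}.
#' @param n_draws Monte-Carlo draws per grid point.
#' @param seed Optional integer seed (each grid point uses a distinct
#'   derived seed).
#'
#' @return A data frame with columns \code{sigma2}, \code{delta},
#'   \code{ent_pi1}, \code{ent_pi2}, \code{ent_pi3}, \code{ent_pi3_se},
#'   \code{diff_ent}.
#' @export
diff_ent_curve <- function(mu, sigma2, a, b, delta_grid,
                           n_draws = 1e5, seed = NULL) {
  stopifnot(all(delta_grid > 0), all(delta_grid < 1),
            !is.unsorted(delta_grid, strictly = TRUE))
  grid <- expand.grid(delta = delta_grid, sigma2 = sigma2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s2 <- grid$sigma2[i]; d <- grid$delta[i]
    e1 <- entropy_closed_form(prior_spec(mu, s2, "unconstrained"))
    e2 <- entropy_closed_form(prior_spec(mu, s2, "certain", a, b))
    e3 <- entropy_mc(prior_spec(mu, s2, "uncertain", a, b, delta = d),
                     n_draws = n_draws,
                     seed = if (is.null(seed)) NULL else seed + i)
    data.frame(sigma2 = s2, delta = d,
               ent_pi1 = e1$value, ent_pi2 = e2$value,
               ent_pi3 = e3$value, ent_pi3_se = e3$mc_se,
               diff_ent = e3$value - e2$value)
  })
  do.call(rbind, rows)
}
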