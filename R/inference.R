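#' Hierarchical screened Gaussian model specification
#'
#' Data model \eqn{y_i = \theta + \epsilon_i}, \eqn{\epsilon_i \sim
#' N(0, \tau^2)}, with \eqn{\tau^2 \sim IG(c, d)} and a two-stage prior
#' on \eqn{\theta}: given \eqn{\theta_0}, \eqn{\theta \sim N(\theta_0,
#' (1-\delta)\sigma^2)}, and \eqn{\theta_0} follows a normal
#' \eqn{N(\mu, \delta\sigma^2)} truncated to \eqn{[a, b]}.  Marginally
#' \eqn{\theta} is the screened normal of [wn_prior()].
#'
#' The inverse gamma is parameterized as shape--rate on the inverse
#' scale: \eqn{IG(c, d)} has density \eqn{\propto
#' (\tau^2)^{-c-1} e^{-d/\tau^2}} and mean \eqn{d/(c-1)} for \eqn{c > 1}.
#'
#' @param mu Prior mean of \eqn{\theta}.
#' @param sigma2 Total prior variance (positive).
#' @param delta Screening proportion in \eqn{[0, 1)}; the variance split
#'   is \eqn{\sigma_0^2 = (1-\delta)\sigma^2}, \eqn{\sigma_1^2 =
#'   \delta\sigma^2}.
#' @param a,b Constraint interval endpoints.
#' @param c,d Inverse-gamma shape and rate for \eqn{\tau^2} (positive).
#'
#' @return An object of class \code{"hsgm_model"}.
#' @export
hsgm_model <- function(mu, sigma2, delta, a, b, c = 2, d = 1) {
  stopifnot(sigma2 > 0, delta >= 0, delta < 1, c > 0, d > 0)
  check_interval(a, b)
  structure(list(mu = mu, sigma2 = sigma2, delta = delta, a = a, b = b,
                 c = c, d = d,
                 sigma0_2 = (1 - delta) * sigma2,
                 sigma1_2 = delta * sigma2),
            class = "hsgm_model")
}

#' @export
print.hsgm_model <- function(x, ...) {
  cat("Hierarchical screened Gaussian model\n")
  cat(sprintf("  theta prior: mu = %g, sigma2 = %g, delta = %g on [%g, %g]\n",
              x$mu, x$sigma2, x$delta, x$a, x$b))
  cat(sprintf("  variance split: sigma0^2 = %g, sigma1^2 = %g\n",
              x$sigma0_2, x$sigma1_2))
  cat(sprintf("  tau2 prior: IG(c = %g, d = %g)\n", x$c, x$d))
  invisible(x)
}

#' Conjugate posterior update for a single observation
#'
#' With \eqn{y \sim N(\theta, \tau^2)} (\eqn{\tau^2} known) and the
#' screened-normal prior, the posterior of \eqn{\theta} is again a
#' weighted normal, \eqn{WN_{(a,b)}(\mu^\ast, \Sigma^\ast)} with
#' \deqn{\mu^\ast = ((1-\delta)\mu + \delta m^\ast,\ m^\ast), \quad
#'   \Sigma^\ast = \begin{pmatrix}
#'     \delta(1-\delta)\sigma^2 + \delta^2 s^{\ast 2} & \delta s^{\ast 2}\\
#'     \delta s^{\ast 2} & s^{\ast 2}
#'   \end{pmatrix},}
#' where \eqn{m^\ast = (\sigma^2 y + \tau^2\mu)/(\sigma^2 + \tau^2)} and
#' \eqn{s^{\ast 2} = \sigma^2\tau^2/(\sigma^2 + \tau^2)} are the usual
#' normal-normal update.
#'
#' @param y A single observation.
#' @param tau2 Known noise variance (positive).
#' @param model An [hsgm_model()].
#'
#' @return A \code{"wn_params"} object for the posterior.
#' @export
conjugate_update <- function(y, tau2, model) {
  stopifnot(inherits(model, "hsgm_model"), length(y) == 1L, tau2 > 0)
  mu <- model$mu; s2 <- model$sigma2; del <- model$delta
  m_star <- (s2 * y + tau2 * mu) / (s2 + tau2)
  s_star2 <- s2 * tau2 / (s2 + tau2)
  Omega <- matrix(c(del * (1 - del) * s2 + del^2 * s_star2, del * s_star2,
                    del * s_star2, s_star2), 2L)
  wn_params(c((1 - del) * mu + del * m_star, m_star), Omega,
            model$a, model$b)
}

#' Full conditional posterior of the mean
#'
#' Given \eqn{\tau^2} and data \eqn{y_1, \dots, y_n}, the conditional
#' posterior of \eqn{\theta} is the weighted normal obtained by applying
#' [conjugate_update()] to \eqn{\bar y} with variance \eqn{\tau^2/n}:
#' \eqn{WN_{(a,b)}(\theta^\ast, \Omega^\ast)} with
#' \eqn{\theta^\ast = (\bar y\sigma^2 + \mu\tau^2/n)/(\sigma^2 +
#' \tau^2/n)} and \eqn{\omega^{\ast 2} = \sigma^2\tau^2/(n\sigma^2 +
#' \tau^2)}.  Its closed-form mean and variance carry the screening
#' corrections \eqn{-\beta_1\kappa} and \eqn{-\beta_2\kappa^2} with
#' \eqn{\kappa = \delta\omega^{\ast 2}/\omega_{11}^\ast}.
#'
#' @param y Numeric data vector.
#' @param tau2 Noise variance (positive).
#' @param model An [hsgm_model()].
#'
#' @return An object of class \code{"hsgm_conditional"}: a list with the
#'   unconstrained update \code{theta_star}, \code{omega_star2}, the
#'   screening-coordinate location \code{theta1_star} and scale
#'   \code{omega11_star2}, the factors \code{kappa}, \code{beta1},
#'   \code{beta2}, the closed-form \code{mean} and \code{variance}, and
#'   the full \code{wn} parameter object.
#' @export
theta_full_conditional <- function(y, tau2, model) {
  stopifnot(inherits(model, "hsgm_model"), length(y) >= 1L, tau2 > 0)
  n <- length(y)
  p <- conjugate_update(mean(y), tau2 / n, model)
  mom <- wn_moments(p)
  structure(list(
    theta_star = p$m[2], omega_star2 = p$Omega[2, 2],
    theta1_star = p$m[1], omega11_star2 = p$Omega[1, 1],
    kappa = mom$kappa, beta1 = mom$beta1, beta2 = mom$beta2,
    mean = mom$mean, variance = mom$variance, wn = p
  ), class = "hsgm_conditional")
}

#' Full conditional posterior of the noise variance
#'
#' Given \eqn{\theta}, the conditional posterior of \eqn{\tau^2} is
#' inverse gamma with shape \eqn{c + n/2} and rate
#' \eqn{d + \frac12 \sum_i (y_i - \theta)^2} (shape--rate on the inverse
#' scale, as in [hsgm_model()]).
#'
#' @param y Numeric data vector.
#' @param theta Current value of the mean.
#' @param model An [hsgm_model()].
#' @return A list with \code{shape} and \code{rate}.
#' @export
tau2_full_conditional <- function(y, theta, model) {
  stopifnot(inherits(model, "hsgm_model"), length(y) >= 1L)
  list(shape = model$c + length(y) / 2,
       rate = model$d + 0.5 * sum((y - theta)^2))
}

#' Constraining effect of the interval screening
#'
#' Decomposes the conditional posterior moments into the unconstrained
#' conjugate part and the signed contribution of the screening:
#' \code{mean_shift = -beta1 * kappa} and \code{variance_reduction =
#' -beta2 * kappa^2}, so that \code{mean - mean_shift = theta_star} and
#' \code{variance - variance_reduction = omega_star2} exactly.  Both
#' terms vanish at \eqn{\delta = 0}.
#'
#' @param cp An \code{"hsgm_conditional"} from [theta_full_conditional()].
#' @return A list with \code{mean_shift} and \code{variance_reduction}.
#' @export
constraining_effect <- function(cp) {
  stopifnot(inherits(cp, "hsgm_conditional"))
  list(mean_shift = -cp$beta1 * cp$kappa,
       variance_reduction = -cp$beta2 * cp$kappa^2)
}

#' Gibbs sampler for the mean and noise variance
#'
#' Alternates the two full conditionals: \eqn{\theta \mid \tau^2} drawn
#' from its weighted-normal conditional via the stochastic
#' representation (one truncated-normal and one normal variate), and
#' \eqn{\tau^2 \mid \theta} drawn from its inverse gamma.  Deterministic
#' under a fixed seed.
#'
#' @param y Numeric data vector.
#' @param model An [hsgm_model()].
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded from the front
#'   (\code{n_iter > burn_in >= 0}).
#' @param seed Optional integer seed.
#' @param init Optional list with \code{theta} and/or \code{tau2} start
#'   values.  Defaults: \eqn{\theta_0 = \bar y} projected to the interval
#'   midpoint when outside \eqn{[a, b]}; \eqn{\tau^2_0} the sample
#'   variance (1 when \eqn{n = 1}).
#' @param fixed_tau2 If supplied, \eqn{\tau^2} is held at this value and
#'   only \eqn{\theta} is updated (useful for checks against the
#'   known-variance conditional).
#'
#' @return An object of class \code{"hsgm_fit"}: post-burn-in chains
#'   \code{theta} and \code{tau2}, effective sample sizes \code{ess},
#'   and the call parameters.
#' @export
hsgm_gibbs <- function(y, model, n_iter = 11000, burn_in = 1000,
                       seed = NULL, init = NULL, fixed_tau2 = NULL) {
  stopifnot(inherits(model, "hsgm_model"), length(y) >= 1L,
            n_iter > burn_in, burn_in >= 0)
  n <- length(y)
  ybar <- mean(y)
  sy <- sum(y)
  syy <- sum(y * y)
  mu <- model$mu; s2 <- model$sigma2; del <- model$delta
  a <- model$a; b <- model$b
  shape <- model$c + n / 2

  theta <- if (!is.null(init$theta)) init$theta else {
    if (ybar >= a && ybar <= b) ybar
    else if (is.finite(a) && is.finite(b)) (a + b) / 2
    else min(max(ybar, a), b)
  }
  tau2 <- if (!is.null(fixed_tau2)) fixed_tau2 else if (!is.null(init$tau2)) {
    init$tau2
  } else if (n > 1) max(var(y), 1e-8) else 1

  th_chain <- numeric(n_iter)
  t2_chain <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      # theta | tau2: weighted-normal full conditional
      w <- tau2 / n
      ths <- (ybar * s2 + mu * w) / (s2 + w)
      os2 <- s2 * w / (s2 + w)
      if (del > 0) {
        th1 <- (1 - del) * mu + del * ths
        o11 <- del * (1 - del) * s2 + del^2 * os2
        o11s <- sqrt(o11)
        zt <- truncnorm::rtruncnorm(1, a = (a - th1) / o11s,
                                    b = (b - th1) / o11s)
        kap <- del * os2 / o11s
        theta <- ths + kap * zt + sqrt(os2 - kap^2) * rnorm(1)
      } else {
        theta <- rnorm(1, ths, sqrt(os2))
      }
      # tau2 | theta: inverse gamma
      if (is.null(fixed_tau2)) {
        rate <- model$d + 0.5 * (syy - 2 * theta * sy + n * theta^2)
        tau2 <- 1 / rgamma(1, shape = shape, rate = rate)
      }
      if (!is.finite(theta) || !is.finite(tau2)) {
        stop("non-finite draw at iteration ", it)
      }
      th_chain[it] <- theta
      t2_chain[it] <- tau2
    }
  })
  keep <- (burn_in + 1):n_iter
  theta_keep <- th_chain[keep]
  tau2_keep <- t2_chain[keep]
  ess <- c(theta = unname(coda::effectiveSize(theta_keep)),
           tau2 = if (is.null(fixed_tau2))
             unname(coda::effectiveSize(tau2_keep)) else NA_real_)
  structure(list(theta = theta_keep, tau2 = tau2_keep, ess = ess,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 model = model, n = n, fixed_tau2 = fixed_tau2),
            class = "hsgm_fit")
}

#' @export
summary.hsgm_fit <- function(object, level = 0.95, ...) {
  pr <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  smry <- function(x) c(mean = mean(x), sd = sd(x), quantile(x, pr))
  out <- rbind(theta = smry(object$theta), tau2 = smry(object$tau2))
  structure(list(stats = out, ess = object$ess, level = level,
                 n_iter = object$n_iter, burn_in = object$burn_in),
            class = "summary.hsgm_fit")
}

#' @export
print.summary.hsgm_fit <- function(x, ...) {
  cat(sprintf("Gibbs posterior summary (%d iterations, %d burn-in)\n",
              x$n_iter, x$burn_in))
  print(round(x$stats, 4))
  cat("Effective sample sizes:",
      paste(names(x$ess), round(x$ess, 1), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.hsgm_fit <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
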