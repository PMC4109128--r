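test_that("conjugate update reduces to the textbook normal posterior at delta = 0", {
  model <- hsgm_model(0, 1, 0, -1, 1, c = 2, d = 1)
  p <- conjugate_update(0.8, 1, model)
  expect_false(p$screened)
  expect_equal(p$m[2], (1 * 0.8 + 1 * 0) / 2)   # (sigma2*y + tau2*mu)/(sigma2+tau2)
  expect_equal(p$Omega[2, 2], 0.5)              # sigma2*tau2/(sigma2+tau2)
})

test_that("an uninformative observation leaves the prior untouched", {
  model <- hsgm_model(0.2, 1.5, 0.4, -1, 1)
  p <- conjugate_update(3, 1e12, model)
  prior <- wn_prior(0.2, 1.5, 0.4, -1, 1)
  expect_equal(p$m, prior$m, tolerance = 1e-10)
  expect_equal(p$Omega, prior$Omega, tolerance = 1e-10)
})

test_that("posterior density is proportional to likelihood times prior", {
  model <- hsgm_model(0, 1, 0.5, -1, 1, c = 2, d = 1)
  prior <- wn_prior(0, 1, 0.5, -1, 1)
  th <- seq(-8, 8, length.out = 321)
  # single observation
  p1 <- conjugate_update(0.8, 1, model)
  lr <- dwn(th, p1, log = TRUE) -
    (dnorm(0.8, th, 1, log = TRUE) + dwn(th, prior, log = TRUE))
  expect_lt(diff(range(lr)), 1e-8)
  # n observations through the mean statistic
  y <- simulate_normal_data(50, 0.3, 1, seed = 2)
  cp <- theta_full_conditional(y, 1.3, model)
  lr2 <- dwn(th, cp$wn, log = TRUE) -
    (dnorm(mean(y), th, sqrt(1.3 / 50), log = TRUE) +
       dwn(th, prior, log = TRUE))
  expect_lt(diff(range(lr2)), 1e-8)
})

test_that("full conditional of theta reduces and decomposes correctly", {
  model <- hsgm_model(0, 1, 0.5, -1, 1)
  # n = 1 equals the single-observation update
  cp1 <- theta_full_conditional(0.8, 1, model)
  p1 <- conjugate_update(0.8, 1, model)
  expect_equal(cp1$wn$m, p1$m)
  expect_equal(cp1$wn$Omega, p1$Omega)
  # constraining-effect identity is exact
  y <- simulate_normal_data(20, 0.3, 1, seed = 3)
  cp <- theta_full_conditional(y, 1, model)
  eff <- constraining_effect(cp)
  expect_identical(cp$mean - eff$mean_shift, cp$theta_star)
  expect_identical(cp$variance - eff$variance_reduction, cp$omega_star2)
  # delta = 0: no constraining effect, plain conjugate moments
  m0 <- hsgm_model(0, 1, 0, -1, 1)
  cp0 <- theta_full_conditional(y, 1, m0)
  expect_equal(cp0$mean, cp0$theta_star)
  expect_equal(cp0$variance, cp0$omega_star2)
  expect_equal(constraining_effect(cp0),
               list(mean_shift = 0, variance_reduction = 0))
  # screening interval symmetric about theta1_star: no mean shift
  cps <- theta_full_conditional(0, 1, hsgm_model(0, 1, 0.5, -2, 2))
  expect_equal(constraining_effect(cps)$mean_shift, 0, tolerance = 1e-12)
})

test_that("full conditional moments match the rejection oracle", {
  model <- hsgm_model(0, 1, 0.5, -1, 1)
  y <- simulate_normal_data(50, 0.3, 1, seed = 5)
  cp <- theta_full_conditional(y, 1, model)
  n <- 1e6
  o <- rwn_reject(n, cp$wn, seed = 6)
  expect_lt(abs(mean(o) - cp$mean), 4 * sqrt(cp$variance / n))
  se_var <- sqrt((mean((o - mean(o))^4) - var(o)^2) / n)
  expect_lt(abs(var(o) - cp$variance), 4 * se_var)
})

test_that("inverse-gamma full conditional has the kernel-consistent parameters", {
  model <- hsgm_model(0, 1, 0.5, -1, 1, c = 2, d = 1)
  # zero residuals leave the prior rate
  fc0 <- tau2_full_conditional(rep(0.4, 6), 0.4, model)
  expect_equal(fc0$shape, 2 + 3)
  expect_equal(fc0$rate, 1)
  # arithmetic: c=2, d=1, n=4, RSS=6 -> (4, 4)
  y <- 0.5 + c(sqrt(1.5), -sqrt(1.5), sqrt(1.5), -sqrt(1.5))  # RSS = 6
  fc <- tau2_full_conditional(y, 0.5, model)
  expect_equal(fc$shape, 4)
  expect_equal(fc$rate, 4)
  # iterating only this conditional reproduces the IG mean
  set.seed(9)
  draws <- 1 / rgamma(1e5, shape = fc$shape, rate = fc$rate)
  expect_lt(abs(mean(draws) - fc$rate / (fc$shape - 1)),
            4 * sd(draws) / sqrt(1e5))
})

test_that("Gibbs with fixed tau2 recovers the conditional posterior", {
  model <- hsgm_model(0, 1, 0.5, -1, 1)
  y <- simulate_normal_data(40, 0.3, 1, seed = 8)
  cp <- theta_full_conditional(y, 1, model)
  fit <- hsgm_gibbs(y, model, n_iter = 20000, burn_in = 0, seed = 10,
                    fixed_tau2 = 1)
  se <- sd(fit$theta) / sqrt(fit$ess["theta"])
  expect_lt(abs(mean(fit$theta) - cp$mean), 4 * se)
  expect_true(all(fit$tau2 == 1))
})

test_that("Gibbs at delta = 0 reproduces the semi-conjugate posterior", {
  model <- hsgm_model(0, 1, 0, -1, 1, c = 2, d = 1)
  y <- simulate_normal_data(30, 0.3, 1, seed = 12)
  oracle <- nig_posterior_oracle(y, 0, 1, 2, 1)
  fit <- hsgm_gibbs(y, model, n_iter = 31000, burn_in = 1000, seed = 13)
  se_t <- sd(fit$theta) / sqrt(fit$ess["theta"])
  se_2 <- sd(fit$tau2) / sqrt(fit$ess["tau2"])
  expect_lt(abs(mean(fit$theta) - oracle$theta_mean), 4 * se_t)
  expect_lt(abs(mean(fit$tau2) - oracle$tau2_mean), 4 * se_2)
  expect_equal(sd(fit$theta), oracle$theta_sd, tolerance = 0.05)
})

test_that("Gibbs output is deterministic under a fixed seed", {
  model <- hsgm_model(0, 1, 0.5, -1, 1)
  y <- simulate_normal_data(20, 0.3, 1, seed = 14)
  f1 <- hsgm_gibbs(y, model, n_iter = 500, burn_in = 100, seed = 15)
  f2 <- hsgm_gibbs(y, model, n_iter = 500, burn_in = 100, seed = 15)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$tau2, f2$tau2)
})

test_that("posterior concentrates on the sample mean as n grows", {
  model <- hsgm_model(0, 1, 0.5, -1, 1)
  sds <- means <- numeric(0)
  for (n in c(100, 10000)) {
    y <- simulate_normal_data(n, 0.3, 1, seed = 16 + n)
    fit <- hsgm_gibbs(y, model, n_iter = 6000, burn_in = 1000, seed = 17)
    means <- c(means, abs(mean(fit$theta) - mean(y)))
    sds <- c(sds, sd(fit$theta))
  }
  expect_lt(means[2], 0.01)
  # posterior sd shrinks roughly like 1/sqrt(n)
  expect_lt(sds[2], sds[1] / 5)
})
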