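test_that("closed-form entropies match quadrature and known identities", {
  # standard normal: (1 + log 2*pi) / 2
  e1 <- entropy_closed_form(prior_spec(0, 1, "unconstrained"))
  expect_equal(e1$value, 0.5 * (1 + log(2 * pi)), tolerance = 1e-12)
  expect_identical(e1$mc_se, 0)
  expect_identical(e1$n_draws, 0)

  # vacuous truncation equals the unconstrained entropy
  e2inf <- entropy_closed_form(prior_spec(0.4, 2, "certain", -Inf, Inf))
  expect_equal(e2inf$value,
               entropy_closed_form(prior_spec(0.4, 2, "unconstrained"))$value,
               tolerance = 1e-12)

  # quadrature agreement for both closed cases
  for (s2 in c(0.5, 1, 2)) {
    sp1 <- prior_spec(0, s2, "unconstrained")
    expect_equal(entropy_closed_form(sp1)$value,
                 quad_entropy(function(t) prior_density(t, sp1)),
                 tolerance = 1e-8)
    sp2 <- prior_spec(0, s2, "certain", -1, 1)
    expect_equal(entropy_closed_form(sp2)$value,
                 quad_entropy(function(t) prior_density(t, sp2), -1, 1),
                 tolerance = 1e-8)
  }

  expect_error(
    entropy_closed_form(prior_spec(0, 1, "uncertain", -1, 1, delta = 0.5)),
    "entropy_mc")
})

test_that("prior densities respect their supports and limits", {
  sp2 <- prior_spec(0, 1, "certain", -1, 1)
  expect_identical(prior_density(c(-2, 2), sp2), c(0, 0))
  # uncertain at delta = 0 coincides with the unconstrained prior
  th <- seq(-5, 5, length.out = 101)
  expect_equal(prior_density(th, prior_spec(0, 1, "uncertain", -1, 1, delta = 0)),
               prior_density(th, prior_spec(0, 1, "unconstrained")),
               tolerance = 1e-14)
  # outside the interval the screened prior is positive but below normal
  sp3 <- prior_spec(0, 1, "uncertain", -1, 1, delta = 0.5)
  expect_gt(prior_density(2, sp3), 0)
  expect_lt(prior_density(2, sp3), dnorm(2))
})

test_that("Monte-Carlo entropy agrees with quadrature and its own limits", {
  # delta = 0: exact normal entropy
  e0 <- entropy_mc(prior_spec(0, 1.5, "uncertain", -1, 1, delta = 0), 1e4)
  expect_equal(e0$value, 0.5 * (1 + log(2 * pi * 1.5)), tolerance = 1e-12)
  expect_identical(e0$mc_se, 0)

  # general case vs quadrature of -int p log p
  sp <- prior_spec(0, 1, "uncertain", -1, 1.5, delta = 0.5)
  e <- entropy_mc(sp, 1e5, seed = 31)
  eq <- quad_entropy(function(t) prior_density(t, sp))
  expect_lt(abs(e$value - eq), 3 * e$mc_se)

  # two disjoint seeds agree within MC error
  e_b <- entropy_mc(sp, 1e5, seed = 77)
  expect_lt(abs(e$value - e_b$value), 6 * max(e$mc_se, e_b$mc_se))

  # near delta = 1 the screened prior approaches the truncated prior.
  # The entropy gap is systematic, of order sqrt(1 - delta) (about 0.0065
  # at delta = 0.9999 by quadrature), so the MC estimate is checked
  # against quadrature at that delta, and the gap is checked to shrink.
  sp_hi <- prior_spec(0, 1, "uncertain", -1, 1, delta = 0.9999)
  e_hi <- entropy_mc(sp_hi, 1e6, seed = 13)
  eq_hi <- quad_entropy(function(t) prior_density(t, sp_hi))
  expect_lt(abs(e_hi$value - eq_hi), 3 * e_hi$mc_se)
  e_tr <- entropy_closed_form(prior_spec(0, 1, "certain", -1, 1))
  gap_hi <- abs(e_hi$value - e_tr$value)
  expect_lt(gap_hi, 0.01)
  e_lo <- entropy_mc(prior_spec(0, 1, "uncertain", -1, 1, delta = 0.999),
                     1e6, seed = 14)
  expect_lt(gap_hi, abs(e_lo$value - e_tr$value))
})

test_that("entropy-gap curve has the documented schema and signs", {
  tab <- diff_ent_curve(0, c(0.5, 2), -1, 0, c(0.2, 0.5, 0.8),
                        n_draws = 2e4, seed = 5)
  expect_named(tab, c("sigma2", "delta", "ent_pi1", "ent_pi2", "ent_pi3",
                      "ent_pi3_se", "diff_ent"))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$diff_ent > 0))
  expect_true(all(tab$ent_pi1 > tab$ent_pi3 & tab$ent_pi3 > tab$ent_pi2))
})
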