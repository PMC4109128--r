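# hsgm: a normal mean under an uncertain interval constraint

Applied analyses often come with soft prior knowledge of the form "the
mean is very likely between *a* and *b*" — a physiological range, a
regulatory limit, a sign constraint with exceptions. Truncating the
prior to `[a, b]` treats that statement as certain and breaks down when
data legitimately fall outside; ignoring it wastes real information.
`hsgm` implements the middle ground: a **hierarchical screened Gaussian
model** in which the interval statement is held with a quantifiable,
controllable degree of uncertainty.

## The model

For data `y_i = θ + ε_i`, `ε_i ~ N(0, τ²)`, `i = 1, …, n`, the prior on
θ is built in two stages:

    τ²        ~ IG(c, d)
    θ  | θ0   ~ N(θ0, (1 − δ)σ²)
    θ0        ~ N(μ, δσ²) truncated to [a, b],        δ ∈ [0, 1)

Marginally θ follows a **weighted (interval-screened) normal**
distribution — the law of the second coordinate of a bivariate normal
with covariance `Σ = σ²[δ, δ; δ, 1]` given that the first (screening)
coordinate lands in `[a, b]`:

    π(θ) = φ(θ; μ, σ²) · [Φ(ξ*v*(b) − η*(θ−μ)) − Φ(ξ*v*(a) − η*(θ−μ))]
                       / [Φ(v*(b)) − Φ(v*(a))],

with `v*(x) = (x−μ)/(σ√δ)`, `ξ* = (1−δ)^(−1/2)`, `η* = ξ*√δ/σ`. This is
simultaneously the maximum-entropy prior given `E[θ] = μ`,
`Var(θ) = σ²` and `P(a ≤ θ ≤ b) = α`, so it interpolates the two
textbook cases: at `δ = 0` it is exactly `N(μ, σ²)` (constraint
ignored), and as `δ → 1` it converges to the doubly truncated normal
(constraint certain).

The package's central quantity is the **objective degree of
uncertainty** the prior assigns to the constraint,

    (1 − α(δ)) × 100%,   α(δ) = Φ̄₂((a,b); μ, Σ) / [Φ(v*(b)) − Φ(v*(a))],

a bivariate-normal conditional rectangle probability. `α(δ)` is
monotone in δ, so a scientist can *prescribe* a degree of uncertainty
(say 20%) and solve for the variance split `σ0² = (1−δ)σ²`,
`σ1² = δσ²` that encodes it — rather than guessing the hierarchy's
variances.

Posterior inference is by conjugacy: the full conditional of θ is again
a weighted normal with closed-form mean `θ* − β₁κ` and variance
`ω*² − β₂κ²` (the `−β₁κ`, `−β₂κ²` terms being the *constraining
effect* of the interval relative to the unconstrained conjugate
update), and τ² is conditionally inverse gamma, so a two-block Gibbs
sampler handles the general case.

## Worked example

Elicit a prior with a 20% degree of uncertainty about θ ∈ [−1, 1.5],
then fit simulated data with true θ = 0.3, τ² = 1:

```r
library(hsgm)

alpha_of_delta(mu = 0, sigma2 = 1, delta = 0.5, a = -1, b = 1.5)
#> Interval constraint [-1, 1.5], delta = 0.5:
#>   alpha = 0.819948  => degree of uncertainty (1 - alpha) = 18.005%
#>   variance split: sigma0^2 = 0.5 (free), sigma1^2 = 0.5 (constrained)

inv <- delta_for_uncertainty(20, mu = 0, sigma2 = 1, a = -1, b = 1.5)
inv$delta
#> [1] 0.3823706

y <- simulate_normal_data(100, theta = 0.3, tau2 = 1, seed = 42)
model <- hsgm_model(mu = 0, sigma2 = 1, delta = inv$delta,
                    a = -1, b = 1.5, c = 2, d = 1)
fit <- hsgm_gibbs(y, model, seed = 42)
summary(fit)
#> Gibbs posterior summary (11000 iterations, 1000 burn-in)
#>         mean     sd   2.5%    50%  97.5%
#> theta 0.3305 0.1039 0.1231 0.3315 0.5350
#> tau2  1.0834 0.1556 0.8198 1.0693 1.4209
#> Effective sample sizes: theta = 10745.4, tau2 = 10000
```

So a δ of 0.382 encodes the requested 20% uncertainty; the posterior
mean 0.33 sits close to the truth 0.3, and the 95% interval
[0.12, 0.53] lies comfortably inside the constraint. The screening's
contribution to the posterior here is tiny
(`constraining_effect(theta_full_conditional(y, mean(fit$tau2), model))`
gives a mean shift of 2e-4), as it should be when the data already
respect the interval: the constraint only bites when data and interval
disagree.

Entropy diagnostics quantify how much prior uncertainty each treatment
of the constraint retains: for μ = 0, σ² = 1, [−1, 1.5],

```r
entropy_closed_form(prior_spec(0, 1, "unconstrained"))$value      # 1.418939
entropy_closed_form(prior_spec(0, 1, "certain", -1, 1.5))$value   # 0.881832
entropy_mc(prior_spec(0, 1, "uncertain", -1, 1.5, delta = 0.5),
           n_draws = 1e5, seed = 42)
#> Differential entropy: 1.325243 nats  (MC, n = 100000, se = 0.00045)
```

— the screened prior (1.325 nats) sits between the unconstrained
(1.419) and truncated (0.882) priors, nearer the former at δ = 0.5.

A command-line driver is installed as `exec/hsgm` with subcommands
`simulate`, `fit`, `uncertainty`, `entropy-curve`, `figures` and
`calibrate`; run it with no arguments for usage.

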