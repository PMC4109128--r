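# Internal numeric helpers shared across the package.

# Validate an interval; either endpoint may be infinite.
check_interval <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (is.nan(a) || is.nan(b)) stop("interval endpoints must not be NaN")
  if (!(a < b)) stop("interval requires a < b (got a = ", a, ", b = ", b, ")")
  invisible(c(a = a, b = b))
}

# Phi(u) - Phi(l), computed through the complementary CDF when both
# arguments sit in the upper tail so the difference does not cancel.
pnorm_diff <- function(l, u) {
  out <- ifelse(l > 0,
    pnorm(l, lower.tail = FALSE) - pnorm(u, lower.tail = FALSE),
    pnorm(u) - pnorm(l)
  )
  pmax(out, 0)
}

# log(Phi(u) - Phi(l)), stable in either tail.  Works elementwise.
log_pnorm_diff <- function(l, u) {
  flip <- is.finite(l) & l > 0
  lo <- ifelse(flip, -u, l)
  hi <- ifelse(flip, -l, u)
  la <- pnorm(hi, log.p = TRUE)
  lb <- pnorm(lo, log.p = TRUE)
  d <- lb - la
  # log(exp(la) - exp(lb)) = la + log1p(-exp(d)); d <= 0 by construction
  res <- la + ifelse(d < -0.693, log1p(-exp(d)), log(-expm1(d)))
  ifelse(is.finite(la), res, -Inf)
}

# x * phi(x) with the tail limits x*phi(x) -> 0 as x -> +-Inf.
xphi <- function(x) ifelse(is.finite(x), x * dnorm(x), 0)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the global RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
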