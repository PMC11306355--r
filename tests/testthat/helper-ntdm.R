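# Shared fixtures and small independent oracles for the test suite.

default_system <- function() smoking_system(smoking_parameters())

# Maximum absolute coefficient difference between two series over the union
# of their exact exponent keys.
fs_max_coef_diff <- function(x, y) {
  key <- union(paste(x$a, x$b), paste(y$a, y$b))
  cx <- stats::setNames(rep(0, length(key)), key)
  cy <- cx
  cx[paste(x$a, x$b)] <- x$coef
  cy[paste(y$a, y$b)] <- y$coef
  if (length(key) == 0L) 0 else max(abs(cx - cy))
}

# Random small series under the session seed set by each property test.
random_series <- function(max_terms = 4, max_exp = 3) {
  n <- sample.int(max_terms, 1L)
  frac_series(coef = round(stats::runif(n, -5, 5), 3),
              a = sample.int(max_exp + 1L, n, replace = TRUE) - 1L,
              b = sample.int(max_exp + 1L, n, replace = TRUE) - 1L)
}

# Riemann-Liouville fractional integral of xi^p at tau, by quadrature with
# the substitution s = (tau - xi)^mu that removes the endpoint singularity:
# (1/Gamma(mu)) int_0^tau (tau-xi)^(mu-1) xi^p dxi
#   = (1/(mu Gamma(mu))) int_0^(tau^mu) (tau - s^(1/mu))^p ds.
rl_integral_quad <- function(p, mu, tau) {
  stats::integrate(function(s) (tau - s^(1 / mu))^p, 0, tau^mu,
                   rel.tol = 1e-12, abs.tol = 0)$value / (mu * gamma(mu))
}

# Truncated Mittag-Leffler sum E_mu(z) = sum_k z^k / Gamma(1 + k mu),
# enough terms that the truncation error is far below the tolerances used.
mittag_leffler <- function(z, mu, kmax = 60) {
  sum(vapply(0:kmax, function(k) z^k * exp(-lgamma(1 + k * mu)), 0))
}

# Least-squares slope of log(err) against log(tau).
loglog_slope <- function(tau, err) {
  unname(stats::coef(stats::lm(log(err) ~ log(tau)))[2])
}
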