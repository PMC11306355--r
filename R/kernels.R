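#' Kernel specification for the NTDM inverse-transform operators
#'
#' The natural transform decomposition method turns each recursion level into
#' one application of a kernel-specific linear operator on fractional power
#' series. The transform pair is applied and inverted analytically, so the
#' operators below act term-wise on monomials \eqn{c\,\tau^p} with
#' \eqn{p = a + b\mu}:
#'
#' * **Caputo** (singular power-law kernel): the order-\eqn{\mu}
#'   Riemann-Liouville integral,
#'   \eqn{c\,\tau^p \mapsto c\,\Gamma(p+1)/\Gamma(p+\mu+1)\,\tau^{p+\mu}}.
#' * **Caputo-Fabrizio** (nonsingular exponential kernel):
#'   \eqn{c\,\tau^p \mapsto (1-\mu)\,c\,\tau^p + \mu\,c/(p+1)\,\tau^{p+1}},
#'   i.e. a convex mix of the identity and one classical integration.
#' * **Atangana-Baleanu-Caputo** (Mittag-Leffler kernel, normalization
#'   \eqn{B(\mu)}):
#'   \eqn{c\,\tau^p \mapsto [(1-\mu)\,c\,\tau^p +
#'   \mu\,c\,\Gamma(p+1)/\Gamma(p+\mu+1)\,\tau^{p+\mu}]/B(\mu)}.
#'
#' At \eqn{\mu = 1} all three reduce to classical integration. The gamma
#' ratios are evaluated through `lgamma()` for stability. \eqn{B(\mu)}
#' defaults to 1, the only normalization consistent with the smoking-model
#' solution components the method produces (none of which carry a
#' normalization factor); it is exposed for completeness.
#'
#' @param kernel one of `"caputo"`, `"cf"`, `"abc"`.
#' @param mu fractional order in `(0, 1]`.
#' @param B_mu positive Atangana-Baleanu normalization \eqn{B(\mu)}
#'   (ignored by the other kernels).
#' @return An object of class `kernel_spec`.
#' @examples
#' sp <- kernel_spec("caputo", mu = 0.8)
#' apply_kernel(sp, fs_constant(1))   # tau^0.8 / gamma(1.8)
#' @export
kernel_spec <- function(kernel = c("caputo", "cf", "abc"), mu, B_mu = 1) {
  kernel <- match.arg(kernel)
  check_mu(mu)
  if (length(B_mu) != 1L || !is.finite(B_mu) || B_mu <= 0) {
    stop("B_mu must be a single positive number", call. = FALSE)
  }
  structure(list(kernel = kernel, mu = mu, B_mu = B_mu),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s, mu = %g%s>\n", x$kernel, x$mu,
              if (x$kernel == "abc") sprintf(", B(mu) = %g", x$B_mu) else ""))
  invisible(x)
}

# Gamma ratio gamma(p+1)/gamma(p+mu+1) via log-gamma; p >= 0 so both
# arguments are >= 1 and the ratio is well conditioned.
gamma_ratio <- function(p, mu) exp(lgamma(p + 1) - lgamma(p + mu + 1))

#' Term-wise fractional inverse-transform operators
#'
#' `apply_caputo()`, `apply_cf()` and `apply_abc()` apply one NTDM recursion
#' step's integral operator to a fractional series (see [kernel_spec] for
#' the term-wise actions). `apply_kernel()` dispatches on a `kernel_spec`.
#' All are linear, exact at the exponent-key level.
#'
#' @param x a [frac_series].
#' @param mu fractional order in `(0, 1]`.
#' @param B_mu positive normalization for the Atangana-Baleanu kernel.
#' @param spec a [kernel_spec].
#' @return A `frac_series`.
#' @export
apply_caputo <- function(x, mu) {
  stopifnot(is_frac_series(x))
  check_mu(mu)
  if (length(x$coef) == 0L) return(fs_empty())
  p <- x$a + x$b * mu
  fs_canonicalize(structure(
    list(a = x$a, b = x$b + 1L, coef = x$coef * gamma_ratio(p, mu)),
    class = "frac_series"))
}

#' @rdname apply_caputo
#' @export
apply_cf <- function(x, mu) {
  stopifnot(is_frac_series(x))
  check_mu(mu)
  if (length(x$coef) == 0L) return(fs_empty())
  p <- x$a + x$b * mu
  fs_canonicalize(structure(
    list(a = c(x$a, x$a + 1L),
         b = c(x$b, x$b),
         coef = c((1 - mu) * x$coef, mu * x$coef / (p + 1))),
    class = "frac_series"))
}

#' @rdname apply_caputo
#' @export
apply_abc <- function(x, mu, B_mu = 1) {
  stopifnot(is_frac_series(x))
  check_mu(mu)
  if (length(x$coef) == 0L) return(fs_empty())
  p <- x$a + x$b * mu
  fs_canonicalize(structure(
    list(a = c(x$a, x$a),
         b = c(x$b, x$b + 1L),
         coef = c((1 - mu) * x$coef, mu * x$coef * gamma_ratio(p, mu)) / B_mu),
    class = "frac_series"))
}

#' @rdname apply_caputo
#' @export
apply_kernel <- function(spec, x) {
  stopifnot(inherits(spec, "kernel_spec"))
  switch(spec$kernel,
         caputo = apply_caputo(x, spec$mu),
         cf     = apply_cf(x, spec$mu),
         abc    = apply_abc(x, spec$mu, spec$B_mu),
         stop("unknown kernel", call. = FALSE))
}
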