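#' Classical fixed-step Runge-Kutta integration (order 4)
#'
#' Integrates the integer-order (\eqn{\mu = 1}) version of a
#' [frac_ode_system] with the classical RK4 scheme on a uniform grid.
#' Used as an independent ground truth for the series solutions at
#' \eqn{\mu = 1}; fully deterministic.
#'
#' @param system a [frac_ode_system].
#' @param t_end final time (`>= h`).
#' @param h step size (`> 0`).
#' @return A tibble with column `tau` and one column per state.
#' @export
rk4_classical <- function(system, t_end, h) {
  stopifnot(inherits(system, "frac_ode_system"), h > 0, t_end >= h)
  nstep <- ceiling(t_end / h - 1e-9)
  taus <- h * (0:nstep)
  out <- matrix(NA_real_, nstep + 1L, system$n)
  x <- system$initial
  out[1L, ] <- x
  f <- function(s) system_rhs(system, s)
  for (i in seq_len(nstep)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x))) {
      stop(sprintf("RK4 blow-up at step %d (tau = %g)", i, taus[i + 1L]),
           call. = FALSE)
    }
    out[i + 1L, ] <- x
  }
  colnames(out) <- system$names
  dplyr::bind_cols(tibble::tibble(tau = taus), tibble::as_tibble(out))
}

#' Fractional Adams-Bashforth-Moulton integration (Caputo)
#'
#' The standard product-trapezoidal predictor-corrector (PECE, one corrector
#' iteration) for Caputo-type systems
#' \eqn{D^\mu_\tau x = f(x)}, \eqn{x(0) = x_0}:
#' \deqn{x^P_{n+1} = x_0 + \frac{1}{\Gamma(\mu)} \sum_{j=0}^{n}
#'   b_{j,n+1} f(x_j), \qquad
#'   x_{n+1} = x_0 + \frac{h^\mu}{\Gamma(\mu+2)}\Big[f(x^P_{n+1}) +
#'   \sum_{j=0}^{n} a_{j,n+1} f(x_j)\Big]}
#' with the usual fractional Adams weights. At \eqn{\mu = 1} the scheme is
#' the classical two-step Adams method and agrees with [rk4_classical] to
#' discretisation accuracy. This is an independent numeric cross-check for
#' the Caputo series solutions; cost is quadratic in the number of steps.
#'
#' @param system a [frac_ode_system].
#' @param mu fractional order in `(0, 1]`.
#' @param t_end final time (`>= h`).
#' @param h step size (`> 0`).
#' @return A tibble with column `tau` and one column per state.
#' @export
abm_caputo <- function(system, mu, t_end, h) {
  stopifnot(inherits(system, "frac_ode_system"), h > 0, t_end >= h)
  check_mu(mu)
  nstep <- ceiling(t_end / h - 1e-9)
  taus <- h * (0:nstep)
  n_states <- system$n
  x0 <- system$initial
  states <- matrix(NA_real_, nstep + 1L, n_states)
  fhist <- matrix(NA_real_, nstep + 1L, n_states)
  states[1L, ] <- x0
  fhist[1L, ] <- system_rhs(system, x0)
  hmu_g1 <- h^mu / gamma(mu + 1)        # folds 1/Gamma(mu) * h^mu/mu
  hmu_g2 <- h^mu / gamma(mu + 2)
  for (np1 in seq_len(nstep)) {
    n <- np1 - 1L
    j <- 0:n
    # predictor weights b_{j,n+1} = h^mu/mu * ((n+1-j)^mu - (n-j)^mu)
    bw <- hmu_g1 * ((n + 1 - j)^mu - (n - j)^mu)
    pred <- x0 + drop(crossprod(fhist[j + 1L, , drop = FALSE], bw))
    # corrector weights a_{j,n+1}
    aw <- numeric(n + 1L)
    aw[1L] <- n^(mu + 1) - (n - mu) * (n + 1)^mu
    if (n >= 1L) {
      jj <- 1:n
      aw[jj + 1L] <- (n - jj + 2)^(mu + 1) + (n - jj)^(mu + 1) -
        2 * (n - jj + 1)^(mu + 1)
    }
    fp <- system_rhs(system, pred)
    xnew <- x0 + hmu_g2 *
      (fp + drop(crossprod(fhist[j + 1L, , drop = FALSE], aw)))
    if (any(!is.finite(xnew))) {
      stop(sprintf("ABM blow-up at step %d (tau = %g)", np1, taus[np1 + 1L]),
           call. = FALSE)
    }
    states[np1 + 1L, ] <- xnew
    fhist[np1 + 1L, ] <- system_rhs(system, xnew)
  }
  colnames(states) <- system$names
  dplyr::bind_cols(tibble::tibble(tau = taus), tibble::as_tibble(states))
}
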