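#' Parameters of the five-compartment smoking epidemic model
#'
#' The model divides a population into potential smokers `V`, occasional
#' smokers `G`, (regular) smokers `T`, temporary quitters `O` and permanent
#' quitters `W`, with dynamics
#' \deqn{D^\mu_\tau V = \alpha - \epsilon V T - \vartheta V}
#' \deqn{D^\mu_\tau G = \epsilon V T - (\varepsilon_1 + \vartheta) G}
#' \deqn{D^\mu_\tau T = \varepsilon_1 G + \varepsilon_2 T O -
#'   (\vartheta + \rho) T}
#' \deqn{D^\mu_\tau O = -\varepsilon_2 T O - \vartheta O +
#'   \rho (1 - \sigma) T}
#' \deqn{D^\mu_\tau W = \sigma \rho T - \vartheta W.}
#' All rates are per unit time; `sigma` is the dimensionless fraction of
#' quitters who quit permanently. Defaults are the reference parameter set
#' and initial compartment counts used throughout the package's worked
#' examples and verification tables.
#'
#' @param alpha recruitment rate into `V` (default 1).
#' @param epsilon effective contact rate between `V` and `T` (default 0.14).
#' @param vartheta natural death rate (default 0.05).
#' @param rho smoking cessation rate (default 0.8).
#' @param sigma fraction of quitters quitting permanently, in `[0, 1]`
#'   (default 0.1).
#' @param eps1 occasional-to-regular smoker transition rate (default 0.002).
#' @param eps2 relapse contact rate between `T` and `O` (default 0.0025).
#' @param V0,G0,T0,O0,W0 initial compartment counts
#'   (defaults 40, 10, 20, 10, 5).
#' @return An object of class `smoking_parameters` (a named list).
#' @export
smoking_parameters <- function(alpha = 1, epsilon = 0.14, vartheta = 0.05,
                               rho = 0.8, sigma = 0.1, eps1 = 0.002,
                               eps2 = 0.0025,
                               V0 = 40, G0 = 10, T0 = 20, O0 = 10, W0 = 5) {
  p <- list(alpha = alpha, epsilon = epsilon, vartheta = vartheta,
            rho = rho, sigma = sigma, eps1 = eps1, eps2 = eps2,
            V0 = V0, G0 = G0, T0 = T0, O0 = O0, W0 = W0)
  if (any(!vapply(p, is.finite, TRUE))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  rates <- c(alpha, epsilon, vartheta, rho, eps1, eps2)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (sigma < 0 || sigma > 1) stop("sigma must be in [0, 1]", call. = FALSE)
  if (any(c(V0, G0, T0, O0, W0) < 0)) {
    stop("initial values must be >= 0", call. = FALSE)
  }
  structure(p, class = "smoking_parameters")
}

#' @export
print.smoking_parameters <- function(x, ...) {
  cat("<smoking_parameters>\n")
  cat(sprintf(
    "  alpha = %g, epsilon = %g, vartheta = %g, rho = %g, sigma = %g\n",
    x$alpha, x$epsilon, x$vartheta, x$rho, x$sigma))
  cat(sprintf("  eps1 = %g, eps2 = %g\n", x$eps1, x$eps2))
  cat(sprintf("  initial: V = %g, G = %g, T = %g, O = %g, W = %g\n",
              x$V0, x$G0, x$T0, x$O0, x$W0))
  invisible(x)
}

#' Read / write smoking-model parameters as JSON
#'
#' The config schema is flat rates plus an `init` block:
#' `{"alpha": ..., "epsilon": ..., "vartheta": ..., "rho": ...,
#' "sigma": ..., "eps1": ..., "eps2": ...,
#' "init": {"V": ..., "G": ..., "T": ..., "O": ..., "W": ...}}`.
#' Missing fields take the defaults of [smoking_parameters()].
#'
#' @param path JSON file path.
#' @param params a `smoking_parameters` object.
#' @return `read_smoking_config()` a `smoking_parameters`;
#'   `write_smoking_config()` the path, invisibly.
#' @export
read_smoking_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- cfg[intersect(names(cfg), c("alpha", "epsilon", "vartheta", "rho",
                                      "sigma", "eps1", "eps2"))]
  if (!is.null(cfg$init)) {
    ini <- cfg$init
    for (s in c("V", "G", "T", "O", "W")) {
      if (!is.null(ini[[s]])) args[[paste0(s, "0")]] <- ini[[s]]
    }
  }
  do.call(smoking_parameters, args)
}

#' @rdname read_smoking_config
#' @export
write_smoking_config <- function(params, path) {
  stopifnot(inherits(params, "smoking_parameters"))
  obj <- list(alpha = params$alpha, epsilon = params$epsilon,
              vartheta = params$vartheta, rho = params$rho,
              sigma = params$sigma, eps1 = params$eps1, eps2 = params$eps2,
              init = list(V = params$V0, G = params$G0, T = params$T0,
                          O = params$O0, W = params$W0))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Build the smoking model as a generic fractional ODE system
#'
#' Encodes the five equations (see [smoking_parameters]) as a
#' [frac_ode_system]: constant source \eqn{(\alpha, 0, 0, 0, 0)}, the linear
#' transfer/death matrix, and the two bilinear interactions
#' \eqn{\epsilon V T} (out of `V`, into `G`) and \eqn{\varepsilon_2 T O}
#' (into `T`, out of `O`). Summing the five right-hand sides cancels every
#' transfer term, leaving \eqn{\alpha - \vartheta N} for the total
#' population \eqn{N}.
#'
#' @param params a [smoking_parameters] object.
#' @return A `frac_ode_system` with states `V, G, T, O, W`.
#' @export
smoking_system <- function(params = smoking_parameters()) {
  stopifnot(inherits(params, "smoking_parameters"))
  p <- params
  L <- matrix(0, 5, 5, dimnames = list(NULL, NULL))
  # V, G, T, O, W = 1..5
  L[1, 1] <- -p$vartheta
  L[2, 2] <- -(p$eps1 + p$vartheta)
  L[3, 2] <- p$eps1
  L[3, 3] <- -(p$vartheta + p$rho)
  L[4, 3] <- p$rho * (1 - p$sigma)
  L[4, 4] <- -p$vartheta
  L[5, 3] <- p$sigma * p$rho
  L[5, 5] <- -p$vartheta
  bl_coef <- c(-p$epsilon, p$epsilon, p$eps2, -p$eps2)
  bl <- tibble::tibble(
    target = c("V", "G", "T", "O"),
    p = c("V", "V", "T", "T"),
    q = c("T", "T", "O", "O"),
    coef = bl_coef)
  frac_ode_system(names = c("V", "G", "T", "O", "W"),
                  constants = c(p$alpha, 0, 0, 0, 0),
                  linear = L, bilinear = bl,
                  initial = c(p$V0, p$G0, p$T0, p$O0, p$W0))
}

r0_denominator <- function(params, T) {
  (params$eps1 + params$vartheta) * (params$vartheta + params$rho) *
    (params$vartheta + params$epsilon * T)
}

#' Basic reproduction number of the smoking model
#'
#' The next-generation construction for the smoking model yields
#' \deqn{R_0 = \frac{\varepsilon_1 \epsilon \vartheta V}
#'   {(\varepsilon_1 + \vartheta)(\vartheta + \rho)
#'    (\vartheta + \epsilon T)},}
#' evaluated at a reference point \eqn{(V, T)}. The construction leaves
#' \eqn{V} and \eqn{T} free, so they are explicit arguments defaulting to
#' the initial compartment values.
#'
#' @param params a [smoking_parameters] object.
#' @param V,T reference compartment values (default the initial values).
#' @return A single number.
#' @examples
#' reproduction_number(smoking_parameters())   # ~0.00445, well below 1
#' @export
reproduction_number <- function(params = smoking_parameters(),
                                V = params$V0, T = params$T0) {
  stopifnot(inherits(params, "smoking_parameters"))
  den <- r0_denominator(params, T)
  if (den <= 0) stop("reproduction number denominator must be > 0",
                     call. = FALSE)
  params$eps1 * params$epsilon * params$vartheta * V / den
}

#' Stability eigenvalue of the smoking-free state
#'
#' The single nonzero eigenvalue \eqn{\lambda} of \eqn{F Q^{-1}} in the
#' next-generation decomposition of the Jacobian equals the reproduction
#' number; the smoking-free state is locally asymptotically stable when
#' \eqn{\lambda < 1}.
#'
#' @inheritParams reproduction_number
#' @return A list with `lambda` and logical `dfe_locally_stable`
#'   (`lambda < 1`).
#' @export
stability_eigenvalue <- function(params = smoking_parameters(),
                                 V = params$V0, T = params$T0) {
  lambda <- reproduction_number(params, V, T)
  list(lambda = lambda, dfe_locally_stable = lambda < 1)
}

#' Sensitivity of the reproduction number to its parameters
#'
#' Analytic partial derivatives of \eqn{R_0} with respect to
#' \eqn{\varepsilon_1}, \eqn{\epsilon}, \eqn{\rho} and \eqn{\vartheta},
#' obtained by differentiating the \eqn{R_0} expression (the \eqn{\vartheta}
#' partial via the log-derivative
#' \eqn{1/\vartheta - 1/(\varepsilon_1+\vartheta) - 1/(\vartheta+\rho) -
#' 1/(\vartheta+\epsilon T)}). Increasing the transition rate
#' \eqn{\varepsilon_1} or the contact rate \eqn{\epsilon} raises \eqn{R_0};
#' increasing the cessation rate \eqn{\rho} lowers it. The sign of the
#' \eqn{\vartheta} partial depends on the parameter point and is reported,
#' not asserted.
#'
#' @inheritParams reproduction_number
#' @return A tibble with columns `parameter`, `dR0` (analytic partial) and
#'   `sign` (`"+"`, `"-"` or `"0"`).
#' @export
sensitivity_partials <- function(params = smoking_parameters(),
                                 V = params$V0, T = params$T0) {
  stopifnot(inherits(params, "smoking_parameters"))
  p <- params
  den <- r0_denominator(p, T)
  if (den <= 0) stop("denominator factors must be > 0", call. = FALSE)
  r0 <- reproduction_number(p, V, T)
  d_eps1 <- p$epsilon * p$vartheta^2 * V /
    ((p$eps1 + p$vartheta)^2 * (p$vartheta + p$rho) *
       (p$vartheta + p$epsilon * T))
  d_eps <- p$eps1 * p$vartheta^2 * V /
    ((p$eps1 + p$vartheta) * (p$vartheta + p$rho) *
       (p$vartheta + p$epsilon * T)^2)
  d_rho <- -p$eps1 * p$epsilon * p$vartheta * V /
    ((p$eps1 + p$vartheta) * (p$vartheta + p$rho)^2 *
       (p$vartheta + p$epsilon * T))
  d_theta <- r0 * (1 / p$vartheta - 1 / (p$eps1 + p$vartheta) -
                     1 / (p$vartheta + p$rho) -
                     1 / (p$vartheta + p$epsilon * T))
  d <- c(eps1 = d_eps1, epsilon = d_eps, rho = d_rho, vartheta = d_theta)
  tibble::tibble(parameter = names(d), dR0 = unname(d),
                 sign = dplyr::case_when(d > 0 ~ "+", d < 0 ~ "-",
                                         TRUE ~ "0"))
}

#' Equilibria of the smoking model
#'
#' The smoking-free equilibrium is the stationary point with all smoking
#' classes empty: \eqn{(\alpha/\vartheta, 0, 0, 0, 0)}. On the endemic
#' branch the non-smoker compartments are explicit functions of the smoker
#' level \eqn{T}:
#' \deqn{V^* = \frac{\alpha}{\epsilon T + \vartheta},\quad
#'   G^* = \frac{\epsilon \alpha T}{(\epsilon T + \vartheta)
#'   (\varepsilon_1 + \vartheta)},\quad
#'   O^* = \frac{\rho (1-\sigma) T}{\varepsilon_2 T + \vartheta},\quad
#'   W^* = \frac{\sigma \rho T}{\vartheta},}
#' and \eqn{T^*} must satisfy the scalar consistency equation
#' \eqn{\varepsilon_1 G^* + \varepsilon_2 T O^* - (\vartheta + \rho) T = 0}.
#' The positive root, when one exists, is found by bracketed bisection; when
#' the bracket scan finds no sign change (as under the default parameters,
#' where \eqn{R_0 < 1}) the endemic entry is reported absent.
#'
#' @param params a [smoking_parameters] object.
#' @param tol absolute bisection tolerance on \eqn{T^*} (default 1e-12).
#' @return A list of class `equilibrium_report`: `dfe` (named 5-vector),
#'   `endemic` (named 5-vector or `NULL`), `endemic_absent_reason`, `R0`,
#'   `lambda`, `dfe_locally_stable`, and `residuals` (max-norm RHS residual
#'   at each reported point).
#' @export
equilibria <- function(params = smoking_parameters(), tol = 1e-12) {
  stopifnot(inherits(params, "smoking_parameters"))
  p <- params
  sys <- smoking_system(p)
  dfe <- c(V = p$alpha / p$vartheta, G = 0, T = 0, O = 0, W = 0)
  endemic_map <- function(T) {
    c(V = p$alpha / (p$epsilon * T + p$vartheta),
      G = p$epsilon * p$alpha * T /
        ((p$epsilon * T + p$vartheta) * (p$eps1 + p$vartheta)),
      T = T,
      O = p$rho * (1 - p$sigma) * T / (p$eps2 * T + p$vartheta),
      W = p$sigma * p$rho * T / p$vartheta)
  }
  g <- function(T) {
    e <- endemic_map(T)
    p$eps1 * e[["G"]] + p$eps2 * T * e[["O"]] - (p$vartheta + p$rho) * T
  }
  # bracket scan for a positive root of the consistency equation
  endemic <- NULL
  reason <- NULL
  lo <- 1e-12
  hi <- max(p$alpha / p$vartheta, sum(sys$initial), 1) * 10
  grid <- exp(seq(log(lo), log(hi), length.out = 400))
  gv <- vapply(grid, g, 0)
  sgn <- which(diff(sign(gv)) != 0)
  if (length(sgn) > 0L) {
    root <- stats::uniroot(g, lower = grid[sgn[1]], upper = grid[sgn[1] + 1L],
                           tol = tol)
    endemic <- endemic_map(root$root)
  } else {
    reason <- "no sign change of the consistency equation on (0, 10*alpha/vartheta]"
  }
  residuals <- c(dfe = max(abs(system_rhs(sys, dfe))))
  if (!is.null(endemic)) {
    residuals["endemic"] <- max(abs(system_rhs(sys, endemic)))
  }
  st <- stability_eigenvalue(p)
  structure(list(dfe = dfe, endemic = endemic,
                 endemic_absent_reason = reason,
                 R0 = reproduction_number(p), lambda = st$lambda,
                 dfe_locally_stable = st$dfe_locally_stable,
                 residuals = residuals),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n")
  cat("  smoking-free equilibrium:",
      paste(sprintf("%s = %.6g", names(x$dfe), x$dfe), collapse = ", "), "\n")
  if (is.null(x$endemic)) {
    cat("  endemic equilibrium: absent (", x$endemic_absent_reason, ")\n",
        sep = "")
  } else {
    cat("  endemic equilibrium:",
        paste(sprintf("%s = %.6g", names(x$endemic), x$endemic),
              collapse = ", "), "\n")
  }
  cat(sprintf("  R0 = lambda = %.6g; smoking-free state locally stable: %s\n",
              x$R0, x$dfe_locally_stable))
  cat(sprintf("  max residuals: %s\n",
              paste(sprintf("%s = %.3g", names(x$residuals), x$residuals),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.equilibrium_report <- function(x, ...) {
  rows <- list(tibble::tibble(point = "dfe", state = names(x$dfe),
                              value = unname(x$dfe)))
  if (!is.null(x$endemic)) {
    rows <- c(rows, list(tibble::tibble(point = "endemic",
                                        state = names(x$endemic),
                                        value = unname(x$endemic))))
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.equilibrium_report <- function(x, ...) {
  tibble::tibble(R0 = x$R0, lambda = x$lambda,
                 dfe_locally_stable = x$dfe_locally_stable,
                 endemic_present = !is.null(x$endemic),
                 max_residual = max(x$residuals))
}
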