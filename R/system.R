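#' Fractional ODE system with constant, linear and bilinear terms
#'
#' Describes a system \eqn{D^\mu_\tau x_i = \kappa_i + \sum_j L_{ij} x_j +
#' \sum c\, x_p x_q} in the solver-generic form the NTDM recursion consumes:
#' a constant source vector, a linear coefficient matrix, and a list of
#' bilinear terms, plus the initial state. Any polynomial compartmental
#' model with at most pairwise products fits this shape.
#'
#' @param names character vector of state labels (length `n`).
#' @param constants numeric `n`-vector of constant source terms
#'   \eqn{\kappa_i}.
#' @param linear numeric `n x n` matrix; `linear[i, j]` is the coefficient
#'   of state `j` in equation `i`.
#' @param bilinear a data frame (or tibble) with columns `target`, `p`, `q`,
#'   `coef`: the term `coef * x_p * x_q` contributes to equation `target`.
#'   Columns `target`, `p`, `q` may be state names or indices. May be `NULL`
#'   or zero rows for a linear system.
#' @param initial numeric `n`-vector of initial values \eqn{x_i(0)}.
#' @return An object of class `frac_ode_system`.
#' @examples
#' # scalar relaxation D^mu x = -x, x(0) = 1
#' sys <- frac_ode_system("x", constants = 0, linear = matrix(-1, 1, 1),
#'                        bilinear = NULL, initial = 1)
#' @export
frac_ode_system <- function(names, constants, linear, bilinear = NULL,
                            initial) {
  n <- length(names)
  stopifnot(n >= 1L, !anyDuplicated(names))
  linear <- as.matrix(linear)
  if (!all(dim(linear) == c(n, n))) {
    stop("linear must be an n x n matrix", call. = FALSE)
  }
  if (length(constants) != n || length(initial) != n) {
    stop("constants and initial must have one entry per state", call. = FALSE)
  }
  if (!all(is.finite(constants), is.finite(linear), is.finite(initial))) {
    stop("all system coefficients must be finite", call. = FALSE)
  }
  if (is.null(bilinear)) {
    bilinear <- tibble::tibble(target = integer(), p = integer(),
                               q = integer(), coef = double())
  } else {
    bilinear <- tibble::as_tibble(bilinear)
    stopifnot(all(c("target", "p", "q", "coef") %in% names(bilinear)))
    to_idx <- function(v) {
      if (is.character(v)) match(v, names) else as.integer(v)
    }
    bilinear$target <- to_idx(bilinear$target)
    bilinear$p <- to_idx(bilinear$p)
    bilinear$q <- to_idx(bilinear$q)
    idx <- c(bilinear$target, bilinear$p, bilinear$q)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n)) {
      stop("bilinear indices out of range or unknown state name",
           call. = FALSE)
    }
    if (any(!is.finite(bilinear$coef))) {
      stop("bilinear coefficients must be finite", call. = FALSE)
    }
  }
  structure(list(n = n, names = as.character(names),
                 constants = as.double(constants), linear = linear,
                 bilinear = bilinear, initial = as.double(initial)),
            class = "frac_ode_system")
}

#' @export
print.frac_ode_system <- function(x, ...) {
  cat(sprintf("<frac_ode_system: %d states (%s), %d bilinear term(s)>\n",
              x$n, paste(x$names, collapse = ", "), nrow(x$bilinear)))
  invisible(x)
}

#' Right-hand side of a fractional ODE system at a state vector
#'
#' Evaluates \eqn{\kappa + L x + \sum c\, x_p x_q} numerically. Used by the
#' classical and fractional verification integrators and for equilibrium
#' residuals.
#'
#' @param system a [frac_ode_system].
#' @param state numeric vector of state values (length `n`).
#' @return Numeric `n`-vector.
#' @export
system_rhs <- function(system, state) {
  stopifnot(inherits(system, "frac_ode_system"),
            length(state) == system$n)
  out <- system$constants + drop(system$linear %*% state)
  bl <- system$bilinear
  if (nrow(bl) > 0L) {
    contrib <- bl$coef * state[bl$p] * state[bl$q]
    for (r in seq_len(nrow(bl))) {
      out[bl$target[r]] <- out[bl$target[r]] + contrib[r]
    }
  }
  out
}
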