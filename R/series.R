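#' Fractional power series: finite sums of monomials c * tau^(a + b*mu)
#'
#' A `frac_series` is a finite linear combination of monomials
#' \eqn{c \, \tau^{a + b\mu}} where the exponent is stored as an *exact*
#' integer pair `(a, b)`: `a` counts plain powers of \eqn{\tau}, `b` counts
#' multiples of the fractional order \eqn{\mu}. This is the closed family in
#' which every component of a natural-transform decomposition solution lives,
#' for all three supported kernels: the Caputo and Atangana-Baleanu operators
#' shift `b`, the Caputo-Fabrizio operator shifts `a`, and bilinear products
#' add exponent pairs. Keeping the pair exact (never a floating value
#' `a + b*mu`) means terms that coincide numerically at special \eqn{\mu}
#' are still held apart, so no spurious merges occur.
#'
#' Terms are stored canonically: unique `(a, b)` keys sorted by `(a, b)`,
#' zero coefficients dropped. Coefficients are doubles; gamma factors arising
#' from fractional integration are absorbed numerically into them.
#'
#' @param coef numeric vector of coefficients (finite).
#' @param a,b integer vectors of the same length as `coef`; both must be
#'   non-negative.
#' @return An object of class `frac_series`: a list with integer vectors
#'   `a`, `b` and a double vector `coef`, all the same length.
#' @examples
#' s <- frac_series(coef = c(40, -113), a = c(0, 0), b = c(0, 1))
#' fs_evaluate(s, tau = 0.1, mu = 1)
#' @export
frac_series <- function(coef = numeric(), a = integer(), b = integer()) {
  stopifnot(length(coef) == length(a), length(coef) == length(b))
  if (any(!is.finite(coef))) {
    stop("frac_series coefficients must be finite", call. = FALSE)
  }
  a <- as.integer(a)
  b <- as.integer(b)
  if (any(a < 0L) || any(b < 0L)) {
    stop("frac_series exponents (a, b) must be non-negative integers",
         call. = FALSE)
  }
  fs_canonicalize(structure(list(a = a, b = b, coef = as.double(coef)),
                            class = "frac_series"))
}

#' @export
#' @rdname frac_series
#' @param x object to test or print.
is_frac_series <- function(x) inherits(x, "frac_series")

# Merge duplicate (a, b) keys, drop exact zeros, sort by (a, b).
# Idempotent; every constructor and operation funnels through here.
fs_canonicalize <- function(x) {
  if (length(x$coef) == 0L) return(fs_empty())
  key <- paste(x$a, x$b)
  coef <- vapply(split(x$coef, key), sum, 0)
  ab <- do.call(rbind, strsplit(names(coef), " ", fixed = TRUE))
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  keep <- coef != 0
  a <- a[keep]; b <- b[keep]; coef <- unname(coef[keep])
  o <- order(a, b)
  structure(list(a = a[o], b = b[o], coef = coef[o]), class = "frac_series")
}

fs_empty <- function() {
  structure(list(a = integer(), b = integer(), coef = double()),
            class = "frac_series")
}

#' Constant series
#'
#' The series with the single term \eqn{c \, \tau^0}; the zero constant
#' gives the empty series. Used to seed NTDM recursions with initial values
#' and constant source terms.
#'
#' @param c a finite number.
#' @return A `frac_series`.
#' @export
fs_constant <- function(c) {
  if (length(c) != 1L || !is.finite(c)) {
    stop("fs_constant() needs a single finite number", call. = FALSE)
  }
  if (c == 0) return(fs_empty())
  frac_series(coef = c, a = 0L, b = 0L)
}

#' Series arithmetic
#'
#' `fs_add()` merges coefficient-wise on exact exponent keys; `fs_scale()`
#' multiplies every coefficient; `fs_multiply()` is the full convolution
#' product, adding exponent pairs term by term. All three return canonical
#' series and are exact at the key level, so the ring axioms hold up to
#' floating arithmetic on coefficients only.
#'
#' @param x,y `frac_series` objects.
#' @param c a finite scalar.
#' @return A `frac_series`.
#' @export
fs_add <- function(x, y) {
  stopifnot(is_frac_series(x), is_frac_series(y))
  fs_canonicalize(structure(
    list(a = c(x$a, y$a), b = c(x$b, y$b), coef = c(x$coef, y$coef)),
    class = "frac_series"))
}

#' @rdname fs_add
#' @export
fs_scale <- function(x, c) {
  stopifnot(is_frac_series(x), length(c) == 1L, is.finite(c))
  fs_canonicalize(structure(
    list(a = x$a, b = x$b, coef = x$coef * c), class = "frac_series"))
}

#' @rdname fs_add
#' @export
fs_multiply <- function(x, y) {
  stopifnot(is_frac_series(x), is_frac_series(y))
  nx <- length(x$coef); ny <- length(y$coef)
  if (nx == 0L || ny == 0L) return(fs_empty())
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  fs_canonicalize(structure(
    list(a = x$a[ix] + y$a[iy],
         b = x$b[ix] + y$b[iy],
         coef = x$coef[ix] * y$coef[iy]),
    class = "frac_series"))
}

#' Evaluate a fractional series
#'
#' Computes \eqn{\sum_j c_j \tau^{a_j + b_j \mu}} at a given \eqn{\tau \ge 0}
#' and \eqn{\mu \in (0, 1]}. Terms are summed in ascending order of the
#' numeric exponent \eqn{a + b\mu} (ties broken by `(b, a)`) so the result
#' is bit-reproducible. Convention at \eqn{\tau = 0}: \eqn{\tau^0 = 1},
#' any positive power is 0.
#'
#' @param x a `frac_series`.
#' @param tau evaluation point(s), each `>= 0`. Vectorised.
#' @param mu fractional order in `(0, 1]`.
#' @return Numeric vector the length of `tau`.
#' @export
fs_evaluate <- function(x, tau, mu) {
  stopifnot(is_frac_series(x))
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  check_mu(mu)
  if (length(x$coef) == 0L) return(rep(0, length(tau)))
  p <- x$a + x$b * mu
  o <- order(p, x$b, x$a)
  p <- p[o]; coef <- x$coef[o]
  vapply(tau, function(t) {
    pow <- ifelse(p == 0, 1, t^p)   # 0^0 = 1 convention
    sum(coef * pow)
  }, 0)
}

check_mu <- function(mu) {
  if (length(mu) != 1L || !is.finite(mu) || mu <= 0 || mu > 1) {
    stop("mu must be a single value in (0, 1]", call. = FALSE)
  }
  invisible(mu)
}

#' Tidy a fractional series into a term table
#'
#' One row per monomial, columns `a`, `b`, `coef`, in canonical order.
#'
#' @param x a `frac_series`.
#' @param ... unused.
#' @return A tibble with columns `a`, `b`, `coef`.
#' @export
tidy.frac_series <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, coef = x$coef)
}

#' @export
print.frac_series <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.frac_series <- function(x, ...) {
  if (length(x$coef) == 0L) return("<frac_series: 0>")
  term <- function(c, a, b) {
    pw <- c(if (a > 0) sprintf("%d", a), if (b > 0) sprintf("%d*mu", b))
    if (length(pw) == 0) sprintf("%.8g", c)
    else sprintf("%.8g * t^(%s)", c, paste(pw, collapse = " + "))
  }
  paste0("<frac_series: ",
         paste(mapply(term, x$coef, x$a, x$b), collapse = " + "), ">")
}

#' Serialize fractional series to and from JSON
#'
#' The JSON form is `{"terms": [{"coef": ..., "a": ..., "b": ...}, ...]}`;
#' a round trip through `fs_to_json()` / `fs_from_json()` reproduces the
#' series exactly (coefficients are written in full double precision).
#'
#' @param x a `frac_series`.
#' @param json a JSON string as produced by `fs_to_json()`.
#' @return `fs_to_json()` a JSON string; `fs_from_json()` a `frac_series`.
#' @export
fs_to_json <- function(x) {
  stopifnot(is_frac_series(x))
  jsonlite::toJSON(
    list(terms = data.frame(coef = x$coef, a = x$a, b = x$b)),
    dataframe = "rows", digits = I(17), auto_unbox = TRUE)
}

#' @rdname fs_to_json
#' @export
fs_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  tm <- obj$terms
  if (is.null(tm) || NROW(tm) == 0L) return(fs_empty())
  frac_series(coef = tm$coef, a = tm$a, b = tm$b)
}
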