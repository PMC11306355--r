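#' Level-k Adomian polynomial of a bilinear product
#'
#' For a bilinear nonlinearity \eqn{x_p x_q} the level-k Adomian polynomial
#' reduces to the Cauchy convolution of the series components,
#' \eqn{A_k = \sum_{j=0}^{k} x_{p,j}\, x_{q,k-j}}.
#'
#' @param components list of lists of [frac_series]:
#'   `components[[i]][[k + 1]]` is level `k` of state `i`.
#' @param p,q state indices of the two factors.
#' @param k level (0-based); components `0..k` of both factors must exist.
#' @return A `frac_series`.
#' @export
adomian_level <- function(components, p, q, k) {
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (length(components[[p]]) < k + 1L || length(components[[q]]) < k + 1L) {
    stop("components up to level k not yet computed", call. = FALSE)
  }
  out <- fs_empty()
  for (j in 0:k) {
    out <- fs_add(out, fs_multiply(components[[p]][[j + 1L]],
                                   components[[q]][[k - j + 1L]]))
  }
  out
}

# Level-k right-hand side R_{i,k} for every state: constant source (per
# source_mode), linear terms on level-k components, Adomian convolution for
# each bilinear term.
rhs_level <- function(system, components, k, source_mode) {
  with_source <- source_mode == "every_level" || k == 0L
  adom <- list()
  bl <- system$bilinear
  rhs <- vector("list", system$n)
  for (i in seq_len(system$n)) {
    r <- if (with_source) fs_constant(system$constants[i]) else fs_empty()
    for (j in seq_len(system$n)) {
      lij <- system$linear[i, j]
      if (lij != 0) r <- fs_add(r, fs_scale(components[[j]][[k + 1L]], lij))
    }
    rhs[[i]] <- r
  }
  if (nrow(bl) > 0L) {
    for (rr in seq_len(nrow(bl))) {
      key <- paste(bl$p[rr], bl$q[rr])
      if (is.null(adom[[key]])) {
        adom[[key]] <- adomian_level(components, bl$p[rr], bl$q[rr], k)
      }
      i <- bl$target[rr]
      rhs[[i]] <- fs_add(rhs[[i]], fs_scale(adom[[key]], bl$coef[rr]))
    }
  }
  rhs
}

#' Solve a fractional ODE system by natural transform decomposition
#'
#' Runs the NTDM recursion: level 0 is the initial state, and level
#' \eqn{k+1} of state \eqn{i} is the kernel's inverse-transform operator
#' applied to the level-\eqn{k} right-hand side
#' \eqn{R_{i,k} = \kappa_i + \sum_j L_{ij} x_{j,k} + \sum c\, A_k(x_p, x_q)}
#' with \eqn{A_k} the Adomian convolution ([adomian_level]). Because every
#' operator maps the monomial family into itself, each component is an exact
#' finite [frac_series] and the whole computation is deterministic —
#' identical inputs give bit-identical output.
#'
#' The constant source \eqn{\kappa_i} is fed into *every* level by default
#' (`source_mode = "every_level"`), the convention under which the
#' smoking-model reference tables were generated; the textbook Adomian
#' alternative (source only at level 0) is available as
#' `source_mode = "first_level"`.
#'
#' @param system a [frac_ode_system].
#' @param spec a [kernel_spec].
#' @param K truncation order: components `k = 0..K` are computed
#'   (default 2, i.e. three components).
#' @param source_mode `"every_level"` (default) or `"first_level"`.
#' @return An object of class `ntdm_solution`: list with the `system`,
#'   `spec`, `K`, `source_mode`, `components` (list: state, then level),
#'   and `partial` (per-state partial-sum `frac_series`).
#' @examples
#' sys <- smoking_system(smoking_parameters())
#' sol <- ntdm_solve(sys, kernel_spec("caputo", mu = 1), K = 2)
#' evaluate_solution(sol, "V", tau = 0.1)   # 30.8717
#' @export
ntdm_solve <- function(system, spec, K = 2,
                       source_mode = c("every_level", "first_level")) {
  stopifnot(inherits(system, "frac_ode_system"),
            inherits(spec, "kernel_spec"))
  source_mode <- match.arg(source_mode)
  if (length(K) != 1L || K < 0 || K != round(K)) {
    stop("K must be a non-negative integer", call. = FALSE)
  }
  K <- as.integer(K)
  components <- lapply(seq_len(system$n),
                       function(i) list(fs_constant(system$initial[i])))
  if (K > 0L) {
    for (k in 0:(K - 1L)) {
      rhs <- rhs_level(system, components, k, source_mode)
      for (i in seq_len(system$n)) {
        comp <- apply_kernel(spec, rhs[[i]])
        if (length(comp$coef) && any(!is.finite(comp$coef))) {
          stop(sprintf("non-finite coefficient in state '%s' at level %d",
                       system$names[i], k + 1L), call. = FALSE)
        }
        components[[i]][[k + 2L]] <- comp
      }
    }
  }
  partial <- lapply(components, function(cs) Reduce(fs_add, cs, fs_empty()))
  names(components) <- system$names
  names(partial) <- system$names
  structure(list(system = system, spec = spec, K = K,
                 source_mode = source_mode,
                 components = components, partial = partial),
            class = "ntdm_solution")
}

#' @export
print.ntdm_solution <- function(x, ...) {
  cat(sprintf(
    "<ntdm_solution: %d states, kernel %s, mu = %g, K = %d (%d components)>\n",
    x$system$n, x$spec$kernel, x$spec$mu, x$K, x$K + 1L))
  invisible(x)
}

#' Evaluate an NTDM partial sum
#'
#' Evaluates the truncated series \eqn{\sum_{k \le K'} x_{i,k}(\tau)} for one
#' state at the solution's fractional order.
#'
#' @param sol an [ntdm_solve] result.
#' @param state state label (or index).
#' @param tau evaluation point(s), `>= 0`.
#' @param upto_k optional lower truncation (defaults to the solution's `K`).
#' @return Numeric vector the length of `tau`.
#' @export
evaluate_solution <- function(sol, state, tau, upto_k = NULL) {
  stopifnot(inherits(sol, "ntdm_solution"))
  i <- if (is.character(state)) match(state, sol$system$names) else
    as.integer(state)
  if (is.na(i) || i < 1L || i > sol$system$n) {
    stop("unknown state: ", state, call. = FALSE)
  }
  if (is.null(upto_k)) {
    s <- sol$partial[[i]]
  } else {
    if (upto_k < 0 || upto_k > sol$K) {
      stop("upto_k must be in 0..K", call. = FALSE)
    }
    s <- Reduce(fs_add, sol$components[[i]][seq_len(upto_k + 1L)], fs_empty())
  }
  fs_evaluate(s, tau, sol$spec$mu)
}

#' Tabulate an NTDM solution on a grid
#'
#' Evaluates every state's partial sum over a `tau` grid and returns a long
#' tibble — the tidy counterpart of the solution's evaluation table.
#'
#' @param x an `ntdm_solution`.
#' @param tau numeric grid (default `seq(0, 0.5, by = 0.1)`).
#' @param ... unused.
#' @return A tibble with columns `tau`, `state`, `value`, `kernel`, `mu`,
#'   `K`.
#' @export
tidy.ntdm_solution <- function(x, tau = seq(0, 0.5, by = 0.1), ...) {
  purrr::map_dfr(x$system$names, function(st) {
    tibble::tibble(tau = tau, state = st,
                   value = evaluate_solution(x, st, tau))
  }) |>
    dplyr::mutate(kernel = x$spec$kernel, mu = x$spec$mu, K = x$K)
}

#' One-row summary of an NTDM solution
#'
#' @param x an `ntdm_solution`.
#' @param ... unused.
#' @return A tibble with kernel, order, truncation and term counts.
#' @export
glance.ntdm_solution <- function(x, ...) {
  tibble::tibble(
    kernel = x$spec$kernel, mu = x$spec$mu, K = x$K,
    n_states = x$system$n,
    n_terms = sum(vapply(x$partial, function(s) length(s$coef), 0L)),
    source_mode = x$source_mode)
}

#' Plot NTDM partial sums
#'
#' Draws each state's truncated series over a `tau` grid, faceted by state.
#'
#' @param object an `ntdm_solution`.
#' @param tau numeric grid.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ntdm_solution <- function(object, tau = seq(0, 0.5, by = 0.01),
                                   ...) {
  df <- tidy(object, tau = tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(
      x = expression(tau), y = "partial sum",
      title = sprintf("NTDM partial sums (%s kernel, mu = %g, K = %d)",
                      object$spec$kernel, object$spec$mu, object$K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Empirical truncation diagnostic
#'
#' A series solution is only trustworthy where the last retained component
#' is small against the partial sum. For each state and grid point this
#' reports the ratio `|last component| / |partial sum|` and flags points
#' where it exceeds `threshold`; `tau_ok` is the largest grid value up to
#' which the state stays below the threshold. This is an empirical check,
#' not a convergence proof.
#'
#' @param sol an [ntdm_solve] result with `K >= 1`.
#' @param tau numeric grid, `>= 0`.
#' @param threshold flag ratio (default 0.05).
#' @return A list with `by_point` (tibble: `state`, `tau`, `ratio`,
#'   `converged`) and `by_state` (tibble: `state`, `tau_ok`).
#' @export
truncation_diagnostic <- function(sol, tau = seq(0, 0.5, by = 0.1),
                                  threshold = 0.05) {
  stopifnot(inherits(sol, "ntdm_solution"))
  if (sol$K < 1L) {
    stop("truncation diagnostic needs at least two components (K >= 1)",
         call. = FALSE)
  }
  mu <- sol$spec$mu
  by_point <- purrr::map_dfr(seq_len(sol$system$n), function(i) {
    last <- fs_evaluate(sol$components[[i]][[sol$K + 1L]], tau, mu)
    tot <- fs_evaluate(sol$partial[[i]], tau, mu)
    tibble::tibble(state = sol$system$names[i], tau = tau,
                   ratio = abs(last) / pmax(abs(tot), .Machine$double.eps))
  }) |>
    dplyr::mutate(converged = .data$ratio <= threshold)
  by_state <- by_point |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      tau_ok = if (any(!.data$converged)) {
        bad <- min(.data$tau[!.data$converged])
        if (any(.data$tau < bad)) max(.data$tau[.data$tau < bad]) else NA_real_
      } else max(.data$tau),
      .groups = "drop")
  list(by_point = by_point, by_state = by_state)
}

#' Export an NTDM solution
#'
#' `solution_to_json()` writes the per-state component series as JSON
#' (`state -> list of {"terms": ...}` objects); `solution_from_json()`
#' restores the list of component series. `write_solution_csv()` writes a
#' tidy evaluation grid (columns `tau,state,value,kernel,mu,K`).
#'
#' @param sol an `ntdm_solution`.
#' @param path file path; for `solution_to_json()` `NULL` returns the JSON
#'   string.
#' @param json JSON string produced by `solution_to_json()`.
#' @param tau evaluation grid for the CSV export.
#' @return See details; `write_solution_csv()` returns the tibble invisibly.
#' @export
solution_to_json <- function(sol, path = NULL) {
  stopifnot(inherits(sol, "ntdm_solution"))
  obj <- lapply(sol$components, function(cs) {
    lapply(cs, function(s) {
      list(terms = data.frame(coef = s$coef, a = s$a, b = s$b))
    })
  })
  json <- jsonlite::toJSON(obj, dataframe = "rows", digits = I(17),
                           auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname solution_to_json
#' @export
solution_from_json <- function(json) {
  if (length(json) == 1L && !grepl("{", json, fixed = TRUE) &&
        file.exists(json)) {
    json <- paste(readLines(json), collapse = "")
  }
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(obj, function(cs) {
    lapply(cs, function(s) {
      tm <- s$terms
      if (length(tm) == 0L) return(fs_empty())
      frac_series(
        coef = vapply(tm, function(t) as.double(t$coef), 0),
        a = vapply(tm, function(t) as.integer(t$a), 0L),
        b = vapply(tm, function(t) as.integer(t$b), 0L))
    })
  })
}

#' @rdname solution_to_json
#' @export
write_solution_csv <- function(sol, path, tau = seq(0, 0.5, by = 0.1)) {
  df <- tidy(sol, tau = tau)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
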