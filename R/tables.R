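#' Reference evaluation tables for the smoking model
#'
#' Reproduces the package's reference table layouts for the smoking model:
#' tables 2-5 give one compartment each (`V`, `T`, `O`, `W`) at fractional
#' orders \eqn{\mu \in \{0.8, 0.9\}}, tables 6-7 give all compartments at
#' \eqn{\mu = 1}; rows are \eqn{\tau \in \{0, 0.1, \ldots, 0.5\}} and the
#' three NTDM columns are the Caputo, Caputo-Fabrizio and
#' Atangana-Baleanu-Caputo partial sums. Columns for the two external
#' comparison methods (q-HATM, LADM) are emitted as `NA` placeholders so the
#' table shape matches; they are never computed here.
#'
#' @param id table number in `2:7`.
#' @param params a [smoking_parameters] object.
#' @param K truncation order (default 2, the reference setting).
#' @param tau row grid (default `seq(0, 0.5, by = 0.1)`).
#' @return A long tibble with columns `table`, `state`, `mu`, `tau`,
#'   `method` (`ntdm_c`, `ntdm_cf`, `ntdm_abc`, `qhatm`, `ladm`), `value`
#'   (full precision; `NA` for the placeholder methods) and `value_4dp`
#'   (half-even rounded to 4 decimals).
#' @examples
#' dplyr::filter(ntdm_table(6), state == "V", tau == 0.1)
#' @export
ntdm_table <- function(id, params = smoking_parameters(), K = 2,
                       tau = seq(0, 0.5, by = 0.1)) {
  if (!(length(id) == 1L && id %in% 2:7)) {
    stop("table id must be one of 2..7", call. = FALSE)
  }
  layout <- list(
    `2` = list(states = "V", mu = c(0.8, 0.9)),
    `3` = list(states = "T", mu = c(0.8, 0.9)),
    `4` = list(states = "O", mu = c(0.8, 0.9)),
    `5` = list(states = "W", mu = c(0.8, 0.9)),
    `6` = list(states = c("V", "G", "T", "O"), mu = 1),
    `7` = list(states = "W", mu = 1))[[as.character(id)]]
  sys <- smoking_system(params)
  kernels <- c(ntdm_c = "caputo", ntdm_cf = "cf", ntdm_abc = "abc")
  ntdm_rows <- purrr::map_dfr(layout$mu, function(mu) {
    purrr::map_dfr(names(kernels), function(meth) {
      sol <- ntdm_solve(sys, kernel_spec(kernels[[meth]], mu = mu), K = K)
      purrr::map_dfr(layout$states, function(st) {
        tibble::tibble(state = st, mu = mu, tau = tau, method = meth,
                       value = evaluate_solution(sol, st, tau))
      })
    })
  })
  placeholder <- tidyr::expand_grid(state = layout$states, mu = layout$mu,
                                    tau = tau,
                                    method = c("qhatm", "ladm")) |>
    dplyr::mutate(value = NA_real_)
  dplyr::bind_rows(ntdm_rows, placeholder) |>
    dplyr::mutate(table = id, value_4dp = round(.data$value, 4),
                  .before = 1) |>
    dplyr::arrange(.data$state, .data$mu, .data$tau,
                   match(.data$method, c(names(kernels), "qhatm", "ladm")))
}

#' Write a reference table to CSV
#'
#' Writes two RFC 4180 CSV files: `<stem>.csv` with values rounded
#' half-even to 4 decimals (the comparison file) and `<stem>_full.csv` at
#' full double precision.
#'
#' @param id table number in `2:7`.
#' @param stem output path without extension.
#' @inheritParams ntdm_table
#' @return The full-precision tibble, invisibly.
#' @export
write_table_csv <- function(id, stem, params = smoking_parameters(), K = 2,
                            tau = seq(0, 0.5, by = 0.1)) {
  df <- ntdm_table(id, params = params, K = K, tau = tau)
  utils::write.csv(dplyr::select(df, -"value"),
                   paste0(stem, ".csv"), row.names = FALSE)
  utils::write.csv(dplyr::select(df, -"value_4dp"),
                   paste0(stem, "_full.csv"), row.names = FALSE)
  invisible(df)
}

#' Equilibrium and sensitivity report for the smoking model
#'
#' Bundles the pieces a stability analysis reads off the model: the
#' equilibrium report ([equilibria]), the reproduction number / stability
#' eigenvalue at the reference point, and the sensitivity partials
#' ([sensitivity_partials]), together with a parameter echo.
#'
#' @inheritParams reproduction_number
#' @return A list with `parameters` (tibble echo), `equilibria`
#'   (`equilibrium_report`), `stability` (list with `lambda`,
#'   `dfe_locally_stable`) and `sensitivity` (tibble).
#' @export
r0_report <- function(params = smoking_parameters(),
                      V = params$V0, T = params$T0) {
  stopifnot(inherits(params, "smoking_parameters"))
  list(
    parameters = tibble::tibble(
      parameter = c("alpha", "epsilon", "vartheta", "rho", "sigma",
                    "eps1", "eps2"),
      value = c(params$alpha, params$epsilon, params$vartheta, params$rho,
                params$sigma, params$eps1, params$eps2)),
    equilibria = equilibria(params),
    stability = stability_eigenvalue(params, V, T),
    sensitivity = sensitivity_partials(params, V, T))
}
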