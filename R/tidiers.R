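# broom-style views of fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a latent-genotype SEM fit
#'
#' @param x A `sem_fit` from [fit_sem()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) {
  est <- x$estimates
  se <- x$se
  z <- est / se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' One-row summary of a latent-genotype SEM fit
#'
#' @param x A `sem_fit` from [fit_sem()].
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `converged`, per-pattern counts
#'   and `nobs`.
#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  n <- x$n_by_pattern
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_both = n[["both"]], n_own_only = n[["own_only"]],
                 n_off_only = n[["offspring_only"]],
                 n_snp_only = n[["snp_only"]], nobs = sum(n))
}

#' Tidy an MR result
#'
#' `mr_result` rows are already tidy; this standardizes the column
#' names to broom conventions.
#'
#' @param x An `mr_result` or `mr_grid` tibble.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `p.value` and
#'   the identifying columns.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  dplyr::rename(tibble::as_tibble(x), term = "method",
                std.error = "se", p.value = "p")
}

#' @rdname tidy.mr_result
#' @method tidy mr_grid
#' @export
tidy.mr_grid <- function(x, ...) {
  tidy.mr_result(x, ...)
}
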