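#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a DSC global fit
#'
#' @param x A `dsc_fit` from [global_fit()].
#' @param all If `FALSE` (default), only free parameters are returned.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high` (95%), `unit`, `free`. Values are
#'   in laboratory units (kJ, K).
#' @export
tidy.dsc_fit <- function(x, all = FALSE, ...) {
  est <- x$estimates
  if (!all) est <- est[est$free, ]
  est
}

#' @rdname tidy.dsc_fit
#' @return For `glance()`: a one-row tibble with `ssr` (J^2), `sigma`
#'   (residual SD, J mol^-1 K^-1), `df.residual`, `nobs`, `n_scans`, `AIC`,
#'   `converged`, `n_starts`.
#' @export
glance.dsc_fit <- function(x, ...) {
  n <- nrow(x$data)
  k <- length(x$free)
  tibble(ssr = x$ssr, sigma = x$sigma, df.residual = x$df.residual,
         nobs = n, n_scans = nrow(x$per_scan),
         AIC = n * log(x$ssr / n) + 2 * k,
         converged = x$converged, n_starts = length(x$start_ssr))
}

#' @rdname tidy.dsc_fit
#' @return For `augment()`: the fitted data with `.fitted` and `.resid`
#'   columns (J mol^-1 K^-1).
#' @export
augment.dsc_fit <- function(x, ...) {
  x$fitted
}
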