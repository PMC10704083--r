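# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an absorbance fit
#'
#' One row per fitted parameter: the peak absorbance followed by the
#' polynomial baseline coefficients.
#'
#' @param x an `absorbance_fit` from [extract_absorbance()].
#' @param ... unused.
#' @return a tibble with columns `term` and `estimate`.
#' @export
tidy.absorbance_fit <- function(x, ...) {
  tibble::tibble(
    term = c("peak_absorbance",
             paste0("baseline_", seq_along(x$baseline_coefficients) - 1L)),
    estimate = c(x$peak_absorbance, x$baseline_coefficients)
  )
}

#' Glance at an absorbance fit
#'
#' @param x an `absorbance_fit` from [extract_absorbance()].
#' @param ... unused.
#' @return a one-row tibble with `peak_absorbance`, `residual_rms`, `snr`,
#'   `converged`, `n_points`.
#' @export
glance.absorbance_fit <- function(x, ...) {
  tibble::tibble(
    peak_absorbance = x$peak_absorbance,
    residual_rms = x$residual_rms,
    snr = x$snr,
    converged = x$converged,
    n_points = x$n_points
  )
}

#' Tidy a KS test result
#'
#' @param x a `ks_result` from [ks_two_sample()].
#' @param ... unused.
#' @return a one-row tibble with `statistic`, `p.value`, `n1`, `n2`,
#'   `comparable`.
#' @export
tidy.ks_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$d_statistic, p.value = x$p_value,
    n1 = x$n1, n2 = x$n2, comparable = x$comparable
  )
}

#' @rdname tidy.ks_result
#' @export
glance.ks_result <- function(x, ...) {
  tidy.ks_result(x, ...)
}
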