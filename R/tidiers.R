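#' Tidy an encoding-model fit
#'
#' @param x An `encoding_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#'   The non-parametric model has no free parameters and returns its fixed
#'   gain with `term = "alpha_fixed"`.
#' @export
tidy.encoding_fit <- function(x, ...) {
  if (x$model == "nonparametric") {
    return(tibble::tibble(term = "alpha_fixed", estimate = x$alpha))
  }
  out <- tibble::tibble(term = "alpha", estimate = x$alpha)
  if (x$model == "weighted") {
    out <- dplyr::bind_rows(out,
                            tibble::tibble(term = "omega", estimate = x$omega))
  }
  out
}

#' Glance at an encoding-model fit
#'
#' @param x An `encoding_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `alpha`, `omega`, `sse`, `n`,
#'   `k`, `bic`, `r2`, `converged`, `identifiable`.
#' @export
glance.encoding_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, alpha = x$alpha, omega = x$omega, sse = x$sse,
    n = x$n, k = x$k, bic = x$bic, r2 = x$r2,
    converged = x$converged, identifiable = x$identifiable
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
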