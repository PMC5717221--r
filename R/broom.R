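#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity
#' with its uncertainty, `glance()` one row of fit-level diagnostics.
#'
#' @param x A `diffusion_fit`, `regime_fit` or `vacf_power_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-methods
NULL

#' @rdname tidy-methods
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D, std.error = x$se,
                 conf.low = x$conf.low, conf.high = x$conf.high)
}

#' @rdname tidy-methods
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, linear = x$linear,
                 n_lags = x$n_lags,
                 window_min = x$window[1], window_max = x$window[2])
}

#' @rdname tidy-methods
#' @method tidy regime_fit
#' @export
tidy.regime_fit <- function(x, ...) {
  tibble::tibble(term = "exponent", estimate = x$exponent,
                 conf.low = x$conf.low, conf.high = x$conf.high)
}

#' @rdname tidy-methods
#' @method glance regime_fit
#' @export
glance.regime_fit <- function(x, ...) {
  tibble::tibble(label = x$label, n_lags = x$n_lags,
                 window_min = x$window[1], window_max = x$window[2])
}

#' @rdname tidy-methods
#' @method tidy vacf_power_fit
#' @export
tidy.vacf_power_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "phi"),
    estimate = c(x$A, x$phi),
    std.error = c(NA_real_, x$phi_se),
    conf.low = c(x$A_conf[1], x$phi_conf[1]),
    conf.high = c(x$A_conf[2], x$phi_conf[2]))
}

#' @rdname tidy-methods
#' @method glance vacf_power_fit
#' @export
glance.vacf_power_fit <- function(x, ...) {
  tibble::tibble(structured = x$structured, resid_acf1 = x$resid_acf1,
                 n_lags = x$n_lags)
}
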