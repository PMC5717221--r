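#' Specify a target velocity autocorrelation function
#'
#' The time-correlated and generalized walks are "data driven": their
#' reorientation kernels are derived from a VACF `g(t)` that is prescribed a
#' priori.  Five families are supported:
#'
#' * `"delta"` — `g(0) = 1`, `g(t) = 0` for `t > 0`: the memoryless classical
#'   walk.
#' * `"exponential"` — `g(t) = exp(alpha t)` with decay rate `alpha < 0`
#'   (per unit time, or per step when `alpha_unit = "per_step"`): the
#'   persistent walk.
#' * `"power_law"` — `g(t) = C0 (Delta / t)^phi` for `t >= Delta`.  `C0` is
#'   the correlation amplitude (`C0 > 0` correlated, `C0 < 0` anticorrelated),
#'   `Delta > 0` the crossover time at which `g = C0`, and `phi > 0` the decay
#'   exponent.  The form diverges as `t -> 0`, so it is only meaningful from
#'   `Delta` on.
#' * `"piecewise_ballistic"` — completely correlated (`g = 1`) up to the time
#'   `t*` at which the power law reaches 1, i.e. `C0 (Delta / t*)^phi = 1`
#'   so `t* = Delta C0^(1/phi)`, and `C0 (Delta/t)^phi` afterwards.  This is
#'   the prescription for crossover times that are not small.
#' * `"tanh_power_law"` — `g(t) = tanh[C0 (Delta / t)^phi]`: the VACF actually
#'   realized by the maximum-caliber (generalized) kernel on the square
#'   lattice when the power law is the constraint target.  Bounded on all of
#'   `t > 0` (it saturates at `sign(C0)` as `t -> 0+`).
#'
#' @param family One of `"delta"`, `"exponential"`, `"power_law"`,
#'   `"piecewise_ballistic"`, `"tanh_power_law"`.
#' @param C0 Correlation amplitude (dimensionless; sign allowed).  Required
#'   for the power-law-type families.  The piecewise family requires
#'   `0 < C0 <= 1` so that `t*` exists.
#' @param Delta Crossover time (time units, `> 0`).
#' @param phi Decay exponent (`> 0`).
#' @param alpha Exponential decay rate (`< 0`); exponential family only.
#' @param alpha_unit `"per_time"` (default) or `"per_step"`; flags whether
#'   `alpha` multiplies continuous time `t` or the step index `k`.
#'
#' @return An object of class `vacf_spec`.  For the piecewise family it
#'   carries the derived ballistic end time `t_star`.
#' @examples
#' vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 0.1)
#' vacf_spec("piecewise_ballistic", C0 = 0.5, Delta = 10, phi = 0.2)$t_star
#' @export
vacf_spec <- function(family = c("delta", "exponential", "power_law",
                                 "piecewise_ballistic", "tanh_power_law"),
                      C0 = NULL, Delta = NULL, phi = NULL,
                      alpha = NULL, alpha_unit = c("per_time", "per_step")) {
  family <- match.arg(family)
  alpha_unit <- match.arg(alpha_unit)
  spec <- list(family = family, C0 = C0, Delta = Delta, phi = phi,
               alpha = alpha, alpha_unit = alpha_unit, t_star = NULL)

  chk <- function(x, nm, positive = FALSE) {
    if (is.null(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("vacf_spec('%s') requires a finite scalar `%s`",
                   family, nm), call. = FALSE)
    }
    if (positive && x <= 0) {
      stop(sprintf("vacf_spec('%s') requires `%s` > 0", family, nm),
           call. = FALSE)
    }
  }

  if (family == "exponential") {
    chk(alpha, "alpha")
    if (alpha > 0) stop("exponential VACF requires alpha <= 0", call. = FALSE)
  } else if (family != "delta") {
    chk(C0, "C0"); chk(Delta, "Delta", positive = TRUE)
    chk(phi, "phi", positive = TRUE)
    if (C0 == 0) stop("power-law-type VACF requires C0 != 0", call. = FALSE)
    if (family == "piecewise_ballistic") {
      if (C0 <= 0 || C0 > 1) {
        stop("piecewise_ballistic requires C0 in (0, 1] so that t* exists",
             call. = FALSE)
      }
      spec$t_star <- Delta * C0^(1 / phi)
    }
  }
  structure(spec, class = "vacf_spec")
}

#' @export
print.vacf_spec <- function(x, ...) {
  par <- switch(x$family,
    delta = "",
    exponential = sprintf(" alpha = %g (%s)", x$alpha, x$alpha_unit),
    sprintf(" C0 = %g, Delta = %g, phi = %g", x$C0, x$Delta, x$phi))
  if (!is.null(x$t_star)) par <- paste0(par, sprintf(", t* = %g", x$t_star))
  cat(sprintf("<vacf_spec> %s%s\n", x$family, par))
  invisible(x)
}

#' Number of ballistic steps of a piecewise VACF
#'
#' The ballistic phase lasts until `t*`; on a lattice with step length `tau`
#' its duration in steps is the smallest integer `omega` with
#' `omega * tau >= t*` (ceiling), which guarantees `g <= 1` at every sampled
#' step thereafter.
#'
#' @param spec A piecewise-ballistic [vacf_spec()].
#' @param tau Time-step duration.
#' @return Integer `omega >= 0`.
#' @examples
#' sp <- vacf_spec("piecewise_ballistic", C0 = 0.5, Delta = 10, phi = 0.2)
#' ballistic_steps(sp, tau = 0.05)  # t* = 0.3125 -> omega = 7
#' @export
ballistic_steps <- function(spec, tau) {
  stopifnot(inherits(spec, "vacf_spec"),
            identical(spec$family, "piecewise_ballistic"),
            is.numeric(tau), tau > 0)
  as.integer(ceiling(spec$t_star / tau - 1e-12))
}

# Plain numeric evaluation of the target VACF; the workhorse behind
# evaluate_target_vacf() and the kernels.  `t` is continuous time unless the
# spec is an exponential flagged per_step, in which case `t` is a step index.
vacf_value <- function(spec, t) {
  stopifnot(inherits(spec, "vacf_spec"))
  switch(spec$family,
    delta = as.numeric(t == 0),
    exponential = exp(spec$alpha * t),
    power_law = {
      if (any(t < spec$Delta - 1e-12)) {
        stop("power-law VACF is undefined for t < Delta ",
             "(the form diverges at short times); use the ",
             "piecewise_ballistic family for large crossover times",
             call. = FALSE)
      }
      spec$C0 * (spec$Delta / t)^spec$phi
    },
    piecewise_ballistic = {
      if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
      ifelse(t <= spec$t_star + 1e-12, 1,
             spec$C0 * (spec$Delta / t)^spec$phi)
    },
    tanh_power_law = {
      if (any(t <= 0)) stop("tanh power-law VACF requires t > 0",
                            call. = FALSE)
      tanh(spec$C0 * (spec$Delta / t)^spec$phi)
    }
  )
}

#' Evaluate a target VACF on a time grid
#'
#' @param spec A [vacf_spec()].
#' @param t Numeric vector of times (step indices for a per-step exponential
#'   spec).  Power-law specs require `t >= Delta`; the tanh family requires
#'   `t > 0`.
#' @return A tibble with columns `t` and `value`, of class `lgca_curve`.
#' @examples
#' sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 1)
#' evaluate_target_vacf(sp, t = c(0.016, 0.16, 1.6))
#' @export
evaluate_target_vacf <- function(spec, t) {
  new_lgca_curve(t, vacf_value(spec, t),
                 meta = list(kind = "vacf", family = spec$family,
                             spec = unclass(spec)))
}

# Shared constructor for theory curves: a tibble (t, value) carrying a meta
# attribute identifying which closed form produced it.
new_lgca_curve <- function(t, value, meta = list()) {
  out <- tibble::tibble(t = as.numeric(t), value = as.numeric(value))
  class(out) <- c("lgca_curve", class(out))
  attr(out, "meta") <- meta
  out
}
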