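#' Local log-log slope of a curve
#'
#' Central finite differences of `log(value)` against `log(t)`, the standard
#' diagnostic for anomalous-diffusion exponents: slope 1 is normal diffusion,
#' `< 1` subdiffusion, `> 1` superdiffusion.
#'
#' @param t Strictly increasing positive time grid.
#' @param value Positive curve values (an MSD, or any power-law-like curve).
#' @return A tibble `(t, slope)` on the interior grid points.
#' @examples
#' t <- 10^seq(0, 4, length.out = 30)
#' loglog_slope(t, t^1.5)$slope   # all 1.5
#' @export
loglog_slope <- function(t, value) {
  stopifnot(length(t) == length(value), length(t) >= 3,
            all(t > 0), all(diff(t) > 0), all(value > 0))
  lt <- log(t); lv <- log(value)
  n <- length(t)
  i <- 2:(n - 1)
  tibble::tibble(t = t[i],
                 slope = (lv[i + 1] - lv[i - 1]) / (lt[i + 1] - lt[i - 1]))
}

#' Transient (speed-dependent) term of the time-correlated MSD
#'
#' The closed-form MSD of the time-correlated walk decomposes into the
#' linear diffusive part, bounded constants, and nonlinear terms
#' `t^{1 - 2 phi}`, `t^{2(1 - phi)}` and `t^{1 - phi}`.  The dominant
#' nonlinear term — the one responsible for the sub/superdiffusive transient
#' — is the squared velocity term
#' \deqn{R(t) = \Big(\frac{v C_0 \Delta^{\varphi}}{\varphi - 1}\Big)^2
#'   t^{2(1-\varphi)}}
#' (logarithmic form `[v C0 Delta ln(Delta/t)]^2` at `phi = 1`).  Its growth
#' exponent `2(1 - phi)` crosses 1 at `phi = 1/2` (end of asymptotic
#' superdiffusion) and 0 at `phi = 1` (disappearance of any transient).
#'
#' @param t Positive time grid.
#' @param spec A power-law-type [vacf_spec()].
#' @param scales A [lattice_scales()].
#' @return An `lgca_curve` tibble `(t, value)`.
#' @export
tc_transient_term <- function(t, spec, scales) {
  stopifnot(inherits(spec, "vacf_spec"), all(t > 0))
  v <- scales$v; C0 <- spec$C0; Delta <- spec$Delta; phi <- spec$phi
  if (abs(phi - 1) < 1e-9) {
    val <- (v * C0 * Delta * log(Delta / t))^2
  } else {
    val <- (v * C0 * Delta^phi / (phi - 1))^2 * t^(2 * (1 - phi))
  }
  new_lgca_curve(t, val, meta = list(kind = "msd_transient",
                                     model = "time_correlated", phi = phi))
}

#' Nonlinear remainder of the stationary generalized MSD
#'
#' The expanded stationary MSD is exactly (for `phi` away from 1 and 2)
#' `a_eff t + K + b t^{2 - phi}` with
#' `a_eff = 2 d D_rw - 2 C0 v^2 Delta / (1 - phi)`,
#' `K = 2 C0 (v Delta)^2 / (2 - phi)` and
#' `b = 2 C0 v^2 Delta^phi / ((1 - phi)(2 - phi))`.  This function removes
#' the linear asymptote and the additive constant and returns the remainder,
#' whose growth exponent `2 - phi` crosses 1 at `phi = 1` (boundary of
#' long-time superdiffusion) and 0 at `phi = 2` (onset of purely normal
#' diffusion).
#'
#' @inheritParams tc_transient_term
#' @return An `lgca_curve` tibble `(t, value)` (values can be negative for
#'   `phi > 1`; the magnitude carries the growth law).
#' @export
gtc_stationary_remainder <- function(t, spec, scales) {
  stopifnot(inherits(spec, "vacf_spec"), all(t > 0))
  v <- scales$v; C0 <- spec$C0; Delta <- spec$Delta; phi <- spec$phi
  if (min(abs(phi - c(1, 2))) < 1e-9) {
    stop("the remainder decomposition applies for phi away from 1 and 2 ",
         "(logarithmic marginal cases)", call. = FALSE)
  }
  msd <- msd_gtc_stationary(t, spec, scales, method = "closed_form")$value
  a_eff <- 2 * scales$d * scales$D_rw - 2 * C0 * v^2 * Delta / (1 - phi)
  K <- 2 * C0 * (v * Delta)^2 / (2 - phi)
  new_lgca_curve(t, msd - a_eff * t - K,
                 meta = list(kind = "msd_remainder",
                             model = "generalized_stationary", phi = phi))
}

# Growth exponent of |curve| by least squares on a log-spaced grid.
fitted_growth_exponent <- function(fun, window, n_grid = 40) {
  t <- exp(seq(log(window[1]), log(window[2]), length.out = n_grid))
  val <- abs(fun(t))
  keep <- val > 0
  stats::coef(stats::lm(log(val[keep]) ~ log(t[keep])))[[2]]
}

# Bisection to a requested tolerance on phi.
bisect_phi <- function(f, lower, upper, tol = 1e-3) {
  fl <- f(lower); fu <- f(upper)
  if (sign(fl) == sign(fu)) {
    stop("bisection bracket does not straddle the boundary", call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid; fl <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

#' Diffusion-regime boundaries of the closed-form MSDs
#'
#' Locates, by bisection on the decay exponent `phi` (to `tol`, default
#' `1e-3`), the boundaries of the diffusion-regime taxonomy, by measuring the
#' growth exponent of the relevant nonlinear part of the closed-form MSD on
#' a log-spaced grid and finding where it crosses the stated threshold:
#'
#' * `regime_boundary_tc()` — the smallest `phi` at which the
#'   time-correlated MSD shows no sub- or superdiffusive transient: the
#'   growth exponent `2(1 - phi)` of the transient term
#'   ([tc_transient_term()]) crosses 0.
#' * `regime_boundary_gtc_superdiffusion()` — the largest `phi` below which
#'   the stationary generalized MSD grows faster than linearly at long
#'   times: the remainder exponent `2 - phi` ([gtc_stationary_remainder()])
#'   crosses 1.
#' * `regime_boundary_gtc_normal()` — the smallest `phi` for which the
#'   stationary generalized MSD is purely normal at all times: the remainder
#'   exponent crosses 0 (the remainder stops growing).
#'
#' Why the nonlinear part and not the raw curve: at any finite crossover
#' time `Delta` the raw MSD slope is biased by the (Green–Kubo enhanced)
#' linear term and by the short-time boundary layer near `Delta`, so its
#' windowed minimum never touches the asymptotic threshold; the nonlinear
#' component isolates exactly the term whose growth the regime taxonomy is
#' about.
#'
#' @param C0,Delta VACF amplitude and crossover time used in the closed
#'   forms.
#' @param scales A [lattice_scales()].
#' @param window Time window (length 2) on which the growth exponent is
#'   measured.
#' @param phi_range Bisection bracket for `phi`.
#' @param tol Bisection tolerance on `phi`.
#' @return The boundary value of `phi`.
#' @examples
#' sc <- lattice_scales(v = 16, D_rw = 1)
#' regime_boundary_tc(C0 = 0.5, Delta = 0.016, scales = sc)   # ~1
#' @export
regime_boundary_tc <- function(C0, Delta, scales,
                               window = c(Delta, 1e6 * Delta),
                               phi_range = c(0.55, 1.45), tol = 1e-3) {
  f <- function(phi) {
    spec <- vacf_spec("power_law", C0 = C0, Delta = Delta, phi = phi)
    fitted_growth_exponent(function(t) tc_transient_term(t, spec, scales)$value,
                           window)
  }
  bisect_phi(f, phi_range[1], phi_range[2], tol)
}

#' @rdname regime_boundary_tc
#' @export
regime_boundary_gtc_superdiffusion <- function(C0, Delta, scales,
                                               window = c(1e6, 1e8),
                                               phi_range = c(0.55, 1.45),
                                               tol = 1e-3) {
  f <- function(phi) {
    if (min(abs(phi - c(1, 2))) < 1e-8) phi <- phi + 1e-7
    spec <- vacf_spec("power_law", C0 = C0, Delta = Delta, phi = phi)
    fitted_growth_exponent(
      function(t) gtc_stationary_remainder(t, spec, scales)$value, window) - 1
  }
  bisect_phi(f, phi_range[1], phi_range[2], tol)
}

#' @rdname regime_boundary_tc
#' @export
regime_boundary_gtc_normal <- function(C0, Delta, scales,
                                       window = c(1e2, 1e8),
                                       phi_range = c(1.55, 2.45),
                                       tol = 1e-3) {
  f <- function(phi) {
    if (min(abs(phi - c(1, 2))) < 1e-8) phi <- phi + 1e-7
    spec <- vacf_spec("power_law", C0 = C0, Delta = Delta, phi = phi)
    fitted_growth_exponent(
      function(t) gtc_stationary_remainder(t, spec, scales)$value, window)
  }
  bisect_phi(f, phi_range[1], phi_range[2], tol)
}
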