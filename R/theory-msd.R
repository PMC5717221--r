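#' Closed-form mean-square displacements
#'
#' All MSD expressions in the package derive from the Taylor–Green–Kubo
#' (TGK) representation of the MSD as sums/integrals over the VACF `g`:
#'
#' * stationary (correlations depend on the lag only, as for the persistent
#'   walk and the pairwise-coupled generalized walk):
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw} t
#'     + 2 v^2 \int_0^t (t - \tau)\, g(\tau)\, d\tau,}
#' * independent orientations (the time-correlated and generalized walks,
#'   whose kernels condition on the initial orientation only):
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw}\Big[t - 2\int_L^t g^2(\tau)
#'     d\tau\Big] + 2 v^2 \int_L^t\!\!\int_\tau^t g(\tau) g(k)\, dk\, d\tau,}
#'   with lower limit `L` the smallest time at which `g` is defined.
#'
#' [msd_numeric_oracle()] evaluates either representation by adaptive
#' quadrature for an arbitrary VACF callable and serves as the independent
#' cross-check of every closed form.
#'
#' @name msd-theory
NULL

#' @describeIn msd-theory Classical walk: normal diffusion,
#'   `<r^2> = 2 d D_rw t` (discrete form `k epsilon^2` at `t = k tau`).
#' @param t Time grid, `>= 0`.
#' @param scales A [lattice_scales()] (supplies `d`, `D_rw`, `v`).
#' @return An `lgca_curve` tibble `(t, value)`.
#' @examples
#' msd_classical(c(0, 5, 10), lattice_scales(v = 16, D_rw = 1))
#' @export
msd_classical <- function(t, scales) {
  stopifnot(inherits(scales, "lattice_scales"), all(t >= 0))
  new_lgca_curve(t, 2 * scales$d * scales$D_rw * t,
                 meta = list(kind = "msd", model = "classical"))
}

#' @describeIn msd-theory Persistent walk, continuum closed form
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw} t (1 - 2/\alpha)
#'     + \Big(\frac{2\sqrt2 d D_{rw}}{v \alpha}\Big)^2
#'       \big[e^{v^2 \alpha t / (2 d D_{rw})} - 1\big],}
#'   with `alpha = ln lambda1 < 0`.  Implemented in the algebraically
#'   identical cancellation-free form
#'   `2 d D_rw t + 2 v^2 (e^{At} - 1 - At)/A^2`, `A = alpha / tau`.
#' @param beta Sensitivity, `> 0`.
#' @param set A [channel_set()].
#' @export
msd_persistent <- function(t, beta, set, scales) {
  stopifnot(inherits(scales, "lattice_scales"), all(t >= 0))
  lambda1 <- persistent_mode_eigenvalue(beta, set)
  if (lambda1 <= 0) {
    stop("persistent MSD closed form requires alpha = ln(lambda1) < 0 with ",
         "lambda1 > 0", call. = FALSE)
  }
  alpha <- log(lambda1)
  A <- alpha / scales$tau   # = alpha v^2 / (2 d D_rw)
  val <- 2 * scales$d * scales$D_rw * t +
    2 * scales$v^2 * (expm1(A * t) - A * t) / A^2
  new_lgca_curve(t, val,
                 meta = list(kind = "msd", model = "persistent",
                             beta = beta, alpha = alpha))
}

#' @describeIn msd-theory Persistent walk, exact discrete-time MSD
#'   \deqn{\langle r_k^2\rangle = 2 d D_{rw} k \tau
#'     + 2 v^2 \sum_{i=1}^{k} (k\tau - i\tau)\, g(i)\, \tau,
#'     \qquad g(i) = \lambda_1^i.}
#' @param k Integer step indices, `>= 0` (vectorized).
#' @export
msd_persistent_discrete <- function(k, beta, set, scales) {
  stopifnot(all(k >= 0), all(k == round(k)))
  lambda1 <- persistent_mode_eigenvalue(beta, set)
  kmax <- max(k)
  g <- lambda1^seq_len(kmax)
  tau <- scales$tau
  s0 <- c(0, cumsum(g))            # sum of g(i), i <= k
  s1 <- c(0, cumsum(seq_len(kmax) * g))  # sum of i g(i)
  val <- 2 * scales$d * scales$D_rw * k * tau +
    2 * scales$v^2 * tau^2 * (k * s0[k + 1] - s1[k + 1])
  new_lgca_curve(k * tau, val,
                 meta = list(kind = "msd", model = "persistent_discrete",
                             beta = beta))
}

#' @describeIn msd-theory Discrete TGK formula for independent orientations:
#'   \deqn{\langle r_k^2\rangle = 2 d D_{rw}\Big[k\tau
#'     - 2 \sum_{i=1}^{k} g^2(i)\,\tau\Big]
#'     + 2 v^2 \sum_{i=1}^{k}\sum_{j=i}^{k} g(i) g(j)\, \tau^2.}
#'   The double sum (which includes the diagonal `j = i`) is evaluated as
#'   `(S1^2 + S2)/2` with `S1 = sum g(i)`, `S2 = sum g(i)^2`.
#' @param g Numeric vector of per-step VACF values `g(1), ..., g(kmax)`.
#' @export
msd_independent_discrete <- function(k, g, scales) {
  stopifnot(all(k >= 0), all(k == round(k)), max(k) <= length(g))
  tau <- scales$tau
  s1 <- c(0, cumsum(g))
  s2 <- c(0, cumsum(g^2))
  S1 <- s1[k + 1]; S2 <- s2[k + 1]
  val <- 2 * scales$d * scales$D_rw * (k * tau - 2 * S2 * tau) +
    2 * scales$v^2 * tau^2 * (S1^2 + S2) / 2
  new_lgca_curve(k * tau, val,
                 meta = list(kind = "msd", model = "independent_discrete"))
}

# Antiderivative helpers for the power-law VACF g(s) = C0 (Delta/s)^phi.
# I1 = int_L^t g ds, I2 = int_L^t g^2 ds; the log forms take over within
# 1e-9 of the singular exponents.
pl_int_g <- function(C0, Delta, phi, L, t) {
  if (abs(phi - 1) < 1e-9) {
    C0 * Delta * log(t / L)
  } else {
    C0 * Delta^phi * (t^(1 - phi) - L^(1 - phi)) / (1 - phi)
  }
}
pl_int_g2 <- function(C0, Delta, phi, L, t) {
  if (abs(phi - 0.5) < 1e-9) {
    C0^2 * Delta * log(t / L)
  } else {
    C0^2 * Delta^(2 * phi) * (t^(1 - 2 * phi) - L^(1 - 2 * phi)) /
      (1 - 2 * phi)
  }
}

#' @describeIn msd-theory Time-correlated walk.  For a bare power-law VACF
#'   (valid from `Delta` on) the continuum TGK integrals evaluate to the
#'   closed forms
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw}\Big[t - 2\int_\Delta^t g^2\Big]
#'     + v^2 \Big(\int_\Delta^t g\Big)^2,}
#'   which expand to the three-regime expressions (general `phi`, and the
#'   logarithmic forms at `phi = 1/2` in the `g^2` integral and `phi = 1` in
#'   the `g` integral).  For a piecewise-ballistic VACF the MSD is
#'   `(v t)^2` during the ballistic phase and, for `t > t*`,
#'   \deqn{2 d D_{rw}\Big[(t - t^*) - 2\int_{t^*}^t g^2\Big]
#'     + v^2\Big[\Big(\int_{t^*}^t g\Big)^2 + 2 t^* \int_{t^*}^t g
#'     + t^{*2}\Big].}
#' @param spec A `power_law` or `piecewise_ballistic` [vacf_spec()].
#' @export
msd_tc <- function(t, spec, scales) {
  stopifnot(inherits(spec, "vacf_spec"), inherits(scales, "lattice_scales"))
  d <- scales$d; D <- scales$D_rw; v <- scales$v
  C0 <- spec$C0; Delta <- spec$Delta; phi <- spec$phi
  if (spec$family == "power_law") {
    if (any(t < Delta - 1e-12)) {
      stop("time-correlated MSD closed form is defined for t >= Delta",
           call. = FALSE)
    }
    I1 <- vapply(t, function(tt) pl_int_g(C0, Delta, phi, Delta, tt),
                 numeric(1))
    I2 <- vapply(t, function(tt) pl_int_g2(C0, Delta, phi, Delta, tt),
                 numeric(1))
    val <- 2 * d * D * (t - 2 * I2) + v^2 * I1^2
  } else if (spec$family == "piecewise_ballistic") {
    ts <- spec$t_star
    stopifnot(all(t >= 0))
    val <- vapply(t, function(tt) {
      if (tt <= ts) return((v * tt)^2)
      I1 <- pl_int_g(C0, Delta, phi, ts, tt)
      I2 <- pl_int_g2(C0, Delta, phi, ts, tt)
      2 * d * D * ((tt - ts) - 2 * I2) + v^2 * (I1^2 + 2 * ts * I1 + ts^2)
    }, numeric(1))
  } else {
    stop("msd_tc requires a power_law or piecewise_ballistic vacf_spec",
         call. = FALSE)
  }
  new_lgca_curve(t, val,
                 meta = list(kind = "msd", model = "time_correlated",
                             family = spec$family,
                             C0 = C0, Delta = Delta, phi = phi))
}

#' @describeIn msd-theory Generalized walk with independent orientations:
#'   the TGK integrals with the realized VACF `tanh[C0 (Delta/tau')^phi]`,
#'   integrated from 0 (the integrand saturates at `sign(C0)` as
#'   `tau' -> 0+`, so it is bounded), evaluated by adaptive quadrature.
#'   Square lattice only (the tanh first moment is `b = 4` specific).
#' @param set A [channel_set()]; must have `b = 4`.
#' @export
msd_gtc <- function(t, spec, scales, set = channel_set(4)) {
  stopifnot(inherits(spec, "vacf_spec"),
            spec$family %in% c("power_law", "tanh_power_law"))
  if (set$b != 4L) {
    stop("generalized-walk MSD closed forms are specific to the square ",
         "lattice (b = 4)", call. = FALSE)
  }
  g <- function(s) tanh(spec$C0 * (spec$Delta / s)^spec$phi)
  val <- msd_numeric_oracle(g, t, scales, lower_limit = 0,
                            form = "independent")
  new_lgca_curve(t, val,
                 meta = list(kind = "msd", model = "generalized",
                             C0 = spec$C0, Delta = spec$Delta,
                             phi = spec$phi))
}

#' @describeIn msd-theory Generalized walk with time-translation-invariant
#'   correlations (the pairwise-coupled, stationary variant):
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw} t
#'     + 2 v^2 \int_0^t (t - \tau) \tanh[C_0 (\Delta/\tau)^{\varphi}] d\tau.}
#'   `method = "quadrature"` evaluates this integral directly;
#'   `method = "closed_form"` (default) evaluates the expansion obtained by
#'   linearizing the hyperbolic tangent and integrating from `Delta`:
#'   \deqn{\langle r_t^2\rangle = 2 d D_{rw} t
#'     + \frac{2 C_0}{1 - \varphi} (v \Delta)^2 \Big\{
#'       \frac{(\Delta/t)^{\varphi - 2} - 1}{2 - \varphi}
#'       + 1 - \frac{t}{\Delta}\Big\}}
#'   for `phi` away from 1 and 2, with the logarithmic forms
#'   `2 C0 (v Delta)^2 {(t/Delta)[ln(t/Delta) - 1] + 1}` at `phi = 1` and
#'   `2 C0 (v Delta)^2 [t/Delta - ln(t/Delta) - 1]` at `phi = 2`.
#'   The long-time behaviour is `t ± t^{2 - phi}`: superdiffusive for
#'   `phi < 1`, transiently subdiffusive for `1 < phi < 2`, and purely
#'   normal for `phi > 2`.
#' @param method `"closed_form"` or `"quadrature"`.
#' @export
msd_gtc_stationary <- function(t, spec, scales,
                               method = c("closed_form", "quadrature"),
                               set = channel_set(4)) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "vacf_spec"),
            spec$family %in% c("power_law", "tanh_power_law"),
            all(t > 0))
  if (set$b != 4L) {
    stop("generalized-walk MSD closed forms are specific to the square ",
         "lattice (b = 4)", call. = FALSE)
  }
  d <- scales$d; D <- scales$D_rw; v <- scales$v
  C0 <- spec$C0; Delta <- spec$Delta; phi <- spec$phi
  if (method == "quadrature") {
    g <- function(s) tanh(C0 * (Delta / s)^phi)
    val <- msd_numeric_oracle(g, t, scales, lower_limit = 0,
                              form = "stationary")
  } else if (abs(phi - 1) < 1e-9) {
    val <- 2 * d * D * t +
      2 * C0 * (v * Delta)^2 * ((t / Delta) * (log(t / Delta) - 1) + 1)
  } else if (abs(phi - 2) < 1e-9) {
    val <- 2 * d * D * t +
      2 * C0 * (v * Delta)^2 * (t / Delta - log(t / Delta) - 1)
  } else {
    val <- 2 * d * D * t + 2 * C0 / (1 - phi) * (v * Delta)^2 *
      (((Delta / t)^(phi - 2) - 1) / (2 - phi) + 1 - t / Delta)
  }
  new_lgca_curve(t, val,
                 meta = list(kind = "msd", model = "generalized_stationary",
                             method = method,
                             C0 = C0, Delta = Delta, phi = phi))
}

#' Adaptive-quadrature TGK oracle
#'
#' Evaluates the MSD directly from the TGK integral representation for an
#' arbitrary VACF callable, by adaptive quadrature ([stats::integrate()],
#' relative tolerance `1e-10`).  The `"independent"` form uses genuinely
#' nested quadrature for the double integral
#' \eqn{\int_L^t g(\tau) \int_\tau^t g(k)\, dk\, d\tau}
#' (it does not shortcut through the square of the single integral), so it
#' is an independent cross-check of the closed forms.
#'
#' @param g A vectorized function of time returning the VACF.
#' @param t Numeric vector of evaluation times, each `> lower_limit`.
#' @param scales A [lattice_scales()].
#' @param lower_limit Lower integration limit `L` (e.g. `Delta` for a bare
#'   power law, 0 for the tanh forms).
#' @param form `"independent"` (TGK with the `-2 int g^2` diffusivity
#'   correction and the nested double integral) or `"stationary"`
#'   (`2 d D_rw t + 2 v^2 int_L^t (t - tau) g(tau) d tau`).
#' @return Numeric vector of MSD values.
#' @examples
#' sc <- lattice_scales(v = 16, D_rw = 1)
#' msd_numeric_oracle(function(s) 0 * s, t = 2, scales = sc,
#'                    lower_limit = 0, form = "stationary")  # 8 = 2 d D t
#' @export
msd_numeric_oracle <- function(g, t, scales, lower_limit = 0,
                               form = c("independent", "stationary")) {
  form <- match.arg(form)
  stopifnot(is.function(g), inherits(scales, "lattice_scales"),
            all(t > lower_limit))
  d <- scales$d; D <- scales$D_rw; v <- scales$v
  quad <- function(f, lo, hi) {
    if (hi <= lo) return(0)
    r <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 500L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected")) {
      stop("quadrature failed to converge: ", r$message, call. = FALSE)
    }
    r$value
  }
  vapply(t, function(tt) {
    if (form == "stationary") {
      2 * d * D * tt + 2 * v^2 * quad(function(s) (tt - s) * g(s),
                                      lower_limit, tt)
    } else {
      inner <- function(s) {
        vapply(s, function(si) quad(g, si, tt), numeric(1))
      }
      2 * d * D * (tt - 2 * quad(function(s) g(s)^2, lower_limit, tt)) +
        2 * v^2 * quad(function(s) g(s) * inner(s), lower_limit, tt)
    }
  }, numeric(1))
}
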