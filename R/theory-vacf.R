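#' Orientation-mode eigenvalue of the persistent kernel
#'
#' The persistent walk's orientations form a homogeneous symmetric Markov
#' chain; its VACF decays geometrically, `g(k) = lambda1^k`, where `lambda1`
#' is the eigenvalue of the transition kernel on the cosine mode of the
#' channel vectors:
#' \deqn{\lambda_1 = \frac{\sum_j (c_0 \cdot c_j) e^{\beta c_0 \cdot c_j}}
#'                        {\sum_j e^{\beta c_0 \cdot c_j}}.}
#' On the 2D square lattice (`b = 4`) this reduces to the closed form
#' `tanh(beta / 2)`, so the per-step decay rate is
#' `alpha = ln lambda1 = ln tanh(beta / 2)`.  For other regular geometries
#' the eigenvalue is computed numerically from the same sum.  At `beta = 0`
#' the kernel is uniform and `lambda1 = 0` (the delta-correlated classical
#' limit).
#'
#' @param beta Sensitivity, `>= 0`.
#' @param set A [channel_set()].
#' @return The scalar eigenvalue `lambda1` in `[0, 1)`.
#' @examples
#' persistent_mode_eigenvalue(5, channel_set(4))  # tanh(2.5)
#' @export
persistent_mode_eigenvalue <- function(beta, set) {
  stopifnot(inherits(set, "channel_set"),
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0)
  a <- drop(set$vectors %*% set$vectors[1, ])
  # subtract max for overflow safety at large beta
  w <- exp(beta * (a - max(a)))
  sum(a * w) / sum(w)
}

#' Persistent-walk VACF in continuous time
#'
#' Continuum limit of the geometric per-step decay:
#' \deqn{g(t) = \exp\!\left(\frac{\alpha v^2}{2 d D_{rw}} t\right),
#'       \qquad \alpha = \ln \lambda_1 < 0,}
#' which at the discrete times `t = k tau` reproduces `lambda1^k` exactly
#' (since `tau = 2 d D_rw / v^2`).
#'
#' @param t Time grid, `>= 0`.
#' @param beta Sensitivity, `> 0`.
#' @param set A [channel_set()].
#' @param scales A [lattice_scales()].
#' @return An `lgca_curve` tibble `(t, value)`.
#' @examples
#' sc <- lattice_scales(v = 16, D_rw = 1)
#' vacf_persistent(c(0, 0.5, 1), beta = 5, set = channel_set(4), scales = sc)
#' @export
vacf_persistent <- function(t, beta, set, scales) {
  stopifnot(inherits(scales, "lattice_scales"), all(t >= 0))
  lambda1 <- persistent_mode_eigenvalue(beta, set)
  if (lambda1 <= 0) {
    stop("persistent-mode eigenvalue is not positive: the exponential VACF ",
         "form does not apply (the chain is in the delta/alternating regime)",
         call. = FALSE)
  }
  alpha <- log(lambda1)
  rate <- alpha * scales$v^2 / (2 * set$d * scales$D_rw)
  new_lgca_curve(t, exp(rate * t),
                 meta = list(kind = "vacf", model = "persistent",
                             beta = beta, alpha = alpha, b = set$b))
}

#' Realized VACF of the generalized (maximum-caliber) walk
#'
#' When the maximum-caliber kernel is constrained toward the power-law target
#' `C0 (Delta/t)^phi`, the VACF it actually realizes on the square lattice is
#' \deqn{g(t) = \tanh[C_0 (\Delta/t)^{\varphi}],}
#' i.e. the first moment `tanh[beta(t)/2]` with Lagrange multiplier
#' `beta(t) = d g_target(t)`.  For `b != 4` the realized first moment is the
#' persistent-mode eigenvalue evaluated at `beta(t)`, computed numerically.
#' A Taylor expansion around `(Delta/t)^phi = 0` recovers the bare power law
#' to second order, so target and realized VACF agree at long times.
#'
#' @param t Time grid, `> 0`.
#' @param spec A power-law [vacf_spec()] (the constraint target).
#' @param set A [channel_set()]; default the square lattice.
#' @return An `lgca_curve` tibble `(t, value)`.
#' @examples
#' sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 1)
#' vacf_generalized(c(0.016, 0.16, 1.6), sp)
#' @export
vacf_generalized <- function(t, spec, set = channel_set(4)) {
  stopifnot(inherits(spec, "vacf_spec"),
            spec$family %in% c("power_law", "tanh_power_law"),
            all(t > 0))
  g_target <- spec$C0 * (spec$Delta / t)^spec$phi
  if (set$b == 4L) {
    # beta(t) = d g = 2 g on the square lattice; tanh(beta/2) = tanh(g)
    val <- tanh(g_target)
  } else {
    a <- drop(set$vectors %*% set$vectors[1, ])
    val <- vapply(set$d * g_target, function(bk) {
      w <- exp(bk * a - max(bk * a))
      sum(a * w) / sum(w)
    }, numeric(1))
  }
  new_lgca_curve(t, val,
                 meta = list(kind = "vacf", model = "generalized",
                             C0 = spec$C0, Delta = spec$Delta,
                             phi = spec$phi, b = set$b))
}

#' Tail exponent of the generalized VACF
#'
#' Where the argument of the hyperbolic tangent is large (short times /
#' strong correlation) the realized VACF
#' `tanh[C0 (Delta/t)^phi]` itself decays as a power law,
#' \deqn{G(t) = \tanh(C_0)\,(\Delta/t)^{2 C_0 \varphi\, \mathrm{csch}(2 C_0)},}
#' with exponent `2 C0 phi csch(2 C0)`.  As `C0 -> 0` the exponent tends to
#' `phi` (the bare power law is recovered).
#'
#' @param C0 Correlation amplitude.
#' @param phi Decay exponent, `> 0`.
#' @return The tail exponent, a positive scalar for `C0 != 0`; `phi` at
#'   `C0 = 0` (the limiting value).
#' @examples
#' generalized_tail_exponent(0.5, 0.2)  # 0.2 / sinh(1)
#' @export
generalized_tail_exponent <- function(C0, phi) {
  stopifnot(is.numeric(C0), length(C0) == 1L, is.finite(C0),
            is.numeric(phi), length(phi) == 1L, phi > 0)
  if (C0 == 0) return(phi)
  2 * C0 * phi / sinh(2 * C0)
}
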