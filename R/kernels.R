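#' Reorientation kernels
#'
#' Each LGCA model is defined by its per-step reorientation probability
#' vector over the `b` velocity channels.  Channel indices are 1-based
#' throughout the package: channel `i` is row `i` of `set$vectors`, i.e. the
#' direction at angle `2 pi (i - 1) / b`.
#'
#' * [classical_probabilities()] — the unbiased walk: every channel with
#'   probability `1/b` at every step.
#' * [persistent_probabilities()] — a Boltzmann-like weight
#'   `exp[beta (c_prev . c_i)]` favouring the previous direction; `beta >= 0`
#'   is the sensitivity (biophysically, the ratio of the effective
#'   reorientation-torque relaxation rate to rotational diffusion).
#' * [tc_probabilities()] — the time-correlated walk: probabilities derived
#'   so the ensemble VACF against the initial orientation equals a prescribed
#'   `g(t)` exactly, `P_i = [1 + d (c_i0 . c_i) g(k tau)] / b`.
#' * [gtc_probabilities()] — the generalized (maximum-caliber) walk:
#'   `P_i = exp[d g(k tau) (c_i0 . c_i)] / z`, always a valid distribution.
#'
#' @name kernels
NULL

#' @describeIn kernels Uniform kernel of the classical walk.
#' @param set A [channel_set()].
#' @return A probability vector of length `set$b`.
#' @examples
#' classical_probabilities(channel_set(4))
#' @export
classical_probabilities <- function(set) {
  stopifnot(inherits(set, "channel_set"))
  rep(1 / set$b, set$b)
}

#' @describeIn kernels Persistent kernel conditioned on the previous channel.
#' @param prev_channel Channel index (1-based) at the previous step.
#' @param beta Sensitivity, finite and `>= 0`.
#' @examples
#' persistent_probabilities(channel_set(4), prev_channel = 1, beta = 5)
#' @export
persistent_probabilities <- function(set, prev_channel, beta) {
  stopifnot(inherits(set, "channel_set"))
  if (length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single finite value >= 0", call. = FALSE)
  }
  check_channel(prev_channel, set)
  a <- drop(set$vectors %*% set$vectors[prev_channel, ])
  w <- exp(beta * a)
  validate_probabilities(w / sum(w))
}

#' @describeIn kernels Time-correlated kernel conditioned on the initial
#'   channel and the step index.  Requires either a `power_law` spec with
#'   `Delta <= tau` (so the divergent short-time part of the power law is
#'   never sampled) or a `piecewise_ballistic` spec, whose first
#'   `omega = ceiling(t*/tau)` steps return the degenerate vector on the
#'   initial channel.  If the resulting linear form goes negative (which
#'   happens while `|g| > 1/d`), a validity error names the offending step
#'   unless `ballistic_extension = TRUE`, in which case the ballistic phase
#'   is extended through that step and the returned vector carries attribute
#'   `ballistic_extended = TRUE`.
#' @param initial_channel Channel index (1-based) at step 0.
#' @param k Step index, `>= 1`.
#' @param spec A [vacf_spec()].
#' @param scales A [lattice_scales()].
#' @param ballistic_extension Logical; opt-in handling of the
#'   `|g| > 1/d` window (default `FALSE`, i.e. raise).
#' @examples
#' sp <- vacf_spec("power_law", C0 = 0.3, Delta = 0.01, phi = 0.5)
#' sc <- lattice_scales(v = 16, D_rw = 1)
#' tc_probabilities(channel_set(4), 1, k = 10, spec = sp, scales = sc)
#' @export
tc_probabilities <- function(set, initial_channel, k, spec, scales,
                             ballistic_extension = FALSE) {
  stopifnot(inherits(set, "channel_set"), inherits(spec, "vacf_spec"),
            inherits(scales, "lattice_scales"))
  check_channel(initial_channel, set)
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single step index >= 1", call. = FALSE)
  }
  tau <- scales$tau
  if (spec$family == "power_law") {
    if (spec$Delta > tau * (1 + 1e-9)) {
      stop("time-correlated kernel with a bare power-law VACF requires ",
           "Delta <= tau; use the piecewise_ballistic family for longer ",
           "crossover times", call. = FALSE)
    }
  } else if (spec$family == "piecewise_ballistic") {
    if (k <= ballistic_steps(spec, tau)) {
      return(one_hot(set$b, initial_channel))
    }
  } else {
    stop("time-correlated kernel requires a power_law or ",
         "piecewise_ballistic vacf_spec", call. = FALSE)
  }
  g <- vacf_value(spec, k * tau)
  d <- set$d
  if (abs(g) > 1 / d + 1e-12) {
    if (ballistic_extension) {
      p <- one_hot(set$b, initial_channel)
      attr(p, "ballistic_extended") <- TRUE
      return(p)
    }
    stop(sprintf(
      "time-correlated kernel invalid at step k = %d: |g(k tau)| = %.6g > 1/d = %.6g yields a negative probability (enable ballistic_extension to extend the ballistic phase)",
      k, abs(g), 1 / d), call. = FALSE)
  }
  a <- drop(set$vectors %*% set$vectors[initial_channel, ])
  validate_probabilities((1 + d * a * g) / set$b)
}

#' @describeIn kernels Generalized (maximum-caliber) kernel.  The Lagrange
#'   multiplier is `beta(k) = d g(k tau)` with `g` the *target* power law
#'   `C0 (Delta/t)^phi` (evaluated bare, at any `t > 0`; the exponential form
#'   keeps the kernel valid even where the target exceeds 1).  On the square
#'   lattice the partition function is `z = 2{1 + cosh[beta(k)]}` and the
#'   realized first moment is `tanh[beta(k)/2]`.
#' @examples
#' gtc_probabilities(channel_set(4), 1, k = 1,
#'                   spec = vacf_spec("power_law", C0 = 0.5, Delta = 0.016,
#'                                    phi = 1),
#'                   scales = lattice_scales(v = 16, D_rw = 1))
#' @export
gtc_probabilities <- function(set, initial_channel, k, spec, scales) {
  stopifnot(inherits(set, "channel_set"), inherits(spec, "vacf_spec"),
            inherits(scales, "lattice_scales"))
  check_channel(initial_channel, set)
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single step index >= 1", call. = FALSE)
  }
  if (!spec$family %in% c("power_law", "tanh_power_law")) {
    stop("generalized kernel requires a power_law (target VACF) spec",
         call. = FALSE)
  }
  t <- k * scales$tau
  g <- spec$C0 * (spec$Delta / t)^spec$phi   # bare target, any t > 0
  if (!is.finite(g)) stop("non-finite target VACF value", call. = FALSE)
  a <- drop(set$vectors %*% set$vectors[initial_channel, ])
  bk_a <- set$d * g * a
  w <- exp(bk_a - max(bk_a))   # overflow-safe for large multipliers
  validate_probabilities(w / sum(w))
}

#' Validate a probability vector
#'
#' Asserts all entries lie in `[-1e-12, 1 + 1e-12]` and the sum is within
#' `1e-12` of 1, clips negative rounding noise to exact zero, and returns the
#' vector; otherwise raises a validity error.
#'
#' @param p Numeric vector.
#' @return `p`, with sub-tolerance negative noise clipped to 0.
#' @examples
#' validate_probabilities(c(0.4, 0.25, 0.1, 0.25))
#' @export
validate_probabilities <- function(p) {
  if (!is.numeric(p) || anyNA(p)) {
    stop("probability vector must be numeric without NAs", call. = FALSE)
  }
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop(sprintf("invalid probability vector: entries outside [0, 1] (min %.3g, max %.3g)",
                 min(p), max(p)), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop(sprintf("invalid probability vector: sum = %.15g != 1", sum(p)),
         call. = FALSE)
  }
  p[p < 0] <- 0
  p
}

check_channel <- function(i, set) {
  if (length(i) != 1L || is.na(i) || i < 1 || i > set$b || i != round(i)) {
    stop(sprintf("channel index must be an integer in 1..%d", set$b),
         call. = FALSE)
  }
  invisible(i)
}

one_hot <- function(b, i) {
  p <- numeric(b)
  p[i] <- 1
  p
}
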