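#' Homogeneous symmetric Markov orientation chains
#'
#' For a walker whose orientation sequence is a homogeneous, symmetric
#' Markov chain on the `b` channels, the VACF can only be delta-correlated,
#' alternating geometric `(-1)^k a^k`, or exponentially decaying
#' `exp(alpha k)` with `alpha <= 0` — never a power law.  This module
#' provides the exact chain VACF (by repeated matrix application) and a
#' classifier of its decay, which together make that trichotomy directly
#' checkable for any admissible chain.
#'
#' "Symmetric" is implemented as: the transition probability depends only on
#' the absolute angular difference between channels, i.e. the matrix is
#' circulant (row `r` is row 1 rotated by `r - 1`) and its first row is
#' reflection-symmetric (`p[1 + j] == p[1 + (b - j) mod b]`).  Matrices
#' violating this are rejected rather than silently classified.
#'
#' @param transition A `b x b` row-stochastic matrix; entry `(i, j)` is the
#'   probability of reorienting from channel `i` to channel `j`.
#' @return An object of class `orientation_chain`.
#' @examples
#' # lazy 1D walker: keep direction with probability 0.9
#' orientation_chain(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
#' @export
orientation_chain <- function(transition) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition),
            nrow(transition) >= 2)
  b <- nrow(transition)
  if (any(transition < -1e-12) ||
      any(abs(rowSums(transition) - 1) > 1e-12)) {
    stop("transition matrix must be row-stochastic (rows sum to 1, ",
         "entries >= 0)", call. = FALSE)
  }
  first <- transition[1, ]
  for (r in seq_len(b)[-1]) {
    rotated <- first[((seq_len(b) - r) %% b) + 1L]
    if (max(abs(transition[r, ] - rotated)) > 1e-12) {
      stop("transition matrix is not circulant (not a homogeneous chain ",
           "over the channel geometry)", call. = FALSE)
    }
  }
  refl <- first[(b - (seq_len(b) - 1L)) %% b + 1L]
  if (max(abs(first - refl)) > 1e-12) {
    stop("transition matrix is not reflection-symmetric (left/right turns ",
         "must be equiprobable)", call. = FALSE)
  }
  structure(list(transition = transition, b = b),
            class = "orientation_chain")
}

#' Transition matrix of the persistent kernel
#'
#' Row `i` is `persistent_probabilities(set, i, beta)`; the resulting chain
#' is circulant and reflection-symmetric by construction, so its VACF decays
#' exponentially with rate `ln(persistent_mode_eigenvalue(beta, set))`.
#'
#' @param set A [channel_set()].
#' @param beta Sensitivity, `>= 0`.
#' @return An [orientation_chain()].
#' @export
persistent_transition_matrix <- function(set, beta) {
  stopifnot(inherits(set, "channel_set"))
  p <- t(vapply(seq_len(set$b),
                function(i) persistent_probabilities(set, i, beta),
                numeric(set$b)))
  orientation_chain(p)
}

#' Exact VACF of an orientation chain
#'
#' Uniform initial orientation and `k`-step transitions give
#' \deqn{g(k) = \frac{1}{b} \sum_{i_0} \sum_{i_k}
#'   (c_{i_0} \cdot c_{i_k}) [P^k]_{i_0 i_k},}
#' computed by repeatedly applying `P` to the channel-vector components
#' (exact up to float precision; no eigendecomposition involved, so this is
#' a brute-force oracle for the decay classifier).
#'
#' @param chain An [orientation_chain()].
#' @param set A [channel_set()] with `b` matching the chain.
#' @param k_max Largest lag, `>= 1`.
#' @return A `curve_series` tibble (`k`, `t = k`, `value`, `sem = 0`).
#' @examples
#' ch <- orientation_chain(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
#' chain_vacf(ch, channel_set(2), k_max = 4)$value   # 1, 0.8, 0.64, ...
#' @export
chain_vacf <- function(chain, set, k_max) {
  stopifnot(inherits(chain, "orientation_chain"),
            inherits(set, "channel_set"), set$b == chain$b, k_max >= 1)
  P <- chain$transition
  V <- set$vectors          # b x 2
  g <- numeric(k_max + 1L)
  g[1L] <- 1
  W <- V
  for (k in seq_len(k_max)) {
    W <- P %*% W            # W[i0, ] = E[c_{i_k} | i_0]
    g[k + 1L] <- sum(V * W) / set$b
  }
  new_curve_series(k = 0:k_max, tau = 1, value = g, sem = 0, n = set$b,
                   meta = list(kind = "vacf", estimator = "chain_exact"))
}

#' Classify the decay of a chain VACF
#'
#' Decides which branch of the trichotomy a VACF sequence belongs to:
#' `"delta"` if `|g(k)| < delta_tol` for all `k >= 1`; otherwise the ratios
#' `|g(k+1)| / |g(k)|` must be constant within `ratio_tol` (geometric
#' decay), with a constant positive sign giving `"exponential"` (rate
#' `alpha = log ratio <= 0`) and a strictly alternating sign giving
#' `"alternating"` (with `a = ratio`).  Anything else — in particular a
#' power law, whose ratios drift — raises a diagnostic error, signalling a
#' non-symmetric or non-homogeneous input.
#'
#' @param g A `curve_series` (or tibble with columns `k`, `value`) with
#'   `g(0) = 1` and at least lags 0..4.
#' @param ratio_tol Tolerance on geometric-ratio constancy (default `1e-9`).
#' @param delta_tol Tolerance for the delta class (default `1e-12`).
#' @param resolvable_floor Ratios whose denominator lag has `|g|` below
#'   this are excluded from the ratio test (their matrix-power values are
#'   dominated by rounding noise); a sequence below the floor already at
#'   lag 1 is reported as `"delta"`, being numerically indistinguishable
#'   from it.
#' @return A list with `class` (`"delta"`, `"alternating"`,
#'   `"exponential"`), `rate` (`alpha` for exponential, `a` for alternating,
#'   `NA` for delta) and `ratio_residual` (worst deviation from ratio
#'   constancy).
#' @examples
#' classify_decay(tibble::tibble(k = 0:5, value = 0.9^(0:5)))
#' @export
classify_decay <- function(g, ratio_tol = 1e-9, delta_tol = 1e-12,
                           resolvable_floor = 2e-6) {
  stopifnot(all(c("k", "value") %in% names(g)))
  g <- g[order(g$k), ]
  if (g$k[1] != 0 || abs(g$value[1] - 1) > 1e-9 || max(g$k) < 4) {
    stop("need a VACF sequence with g(0) = 1 and k_max >= 4", call. = FALSE)
  }
  v <- g$value[g$k >= 1]
  if (all(abs(v) < delta_tol)) {
    return(list(class = "delta", rate = NA_real_, ratio_residual = 0))
  }
  # A ratio g(k+1)/g(k) computed from matrix powers carries absolute error
  # ~ eps_machine / |g(k)|, so only ratios whose *denominator* lag is above
  # the resolvability floor certify the decay.  A sequence already below
  # the floor at lag 1 is numerically indistinguishable from delta.
  m <- 0L
  while (m < length(v) - 1L && abs(v[m + 1L]) > resolvable_floor) {
    m <- m + 1L
  }
  if (m == 0L) {
    # below the floor no ratio is certifiable; the sequence is delta at
    # numerical resolution
    return(list(class = "delta", rate = NA_real_, ratio_residual = 0))
  }
  used <- v[seq_len(m + 1L)]
  ratios <- abs(used[-1]) / abs(used[-length(used)])
  resid <- max(abs(ratios - ratios[1]))
  if (!is.finite(resid) || resid > ratio_tol) {
    stop(sprintf(
      "VACF is not geometric within tolerance (ratio residual %.3g): input is not a homogeneous symmetric chain VACF",
      resid), call. = FALSE)
  }
  signs <- sign(used)
  if (all(signs > 0)) {
    list(class = "exponential", rate = log(ratios[1]),
         ratio_residual = resid)
  } else if (all(signs == (-1)^seq_along(used))) {
    list(class = "alternating", rate = ratios[1], ratio_residual = resid)
  } else {
    stop("sign pattern is neither constant positive nor strictly ",
         "alternating: unclassifiable VACF", call. = FALSE)
  }
}
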