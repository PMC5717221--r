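# Shared fixtures: the reference square-lattice geometry and figure-caption
# scales (v = 16, D_rw = 1 => epsilon = 0.25, tau = 0.015625), built in code.

ref_channels <- channel_set(4)
ref_scales <- lattice_scales(v = 16, D_rw = 1, d = 2)

# A random symmetric circulant transition row for b channels: random
# nonnegative weights on the half-spectrum of angular differences,
# mirrored and normalized.
random_symmetric_chain <- function(b) {
  half <- floor(b / 2)
  w <- stats::runif(half + 1)^2
  row <- numeric(b)
  row[1] <- w[1]
  for (j in seq_len(half)) {
    row[j + 1] <- w[j + 1]
    row[(b - j) %% b + 1] <- w[j + 1]
  }
  row <- row / sum(row)
  P <- t(vapply(seq_len(b),
                function(r) row[((seq_len(b) - r) %% b) + 1],
                numeric(b)))
  orientation_chain(P)
}

# Exact per-step first moments realized by the reference kernels, for the
# discrete TGK comparisons.
realized_g_tc <- function(spec, scales, k) {
  om <- if (spec$family == "piecewise_ballistic") {
    ballistic_steps(spec, scales$tau)
  } else 0L
  ifelse(k <= om, 1, spec$C0 * (spec$Delta / (k * scales$tau))^spec$phi)
}

realized_g_gtc <- function(spec, scales, k) {
  tanh(spec$C0 * (spec$Delta / (k * scales$tau))^spec$phi)
}
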