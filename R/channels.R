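#' Velocity channels of a lattice-gas cellular automaton node
#'
#' An LGCA node carries `b` unit velocity channels
#' \eqn{c_j = (\cos 2\pi j/b, \sin 2\pi j/b)}, `j = 0, ..., b - 1`.
#' At every time step a walker adopts one channel probabilistically and is
#' then translocated deterministically to the neighbouring node in that
#' direction.  The effective spatial dimension is `d = 1` for the two-channel
#' lattice (both channels lie on the x-axis) and `d = 2` for every `b >= 3`;
#' this is the `d` that enters the time-correlated reorientation kernel and
#' the diffusion coefficient.
#'
#' The returned object satisfies two geometric identities used throughout the
#' theory: the channels sum to the zero vector (isotropy), and for every
#' fixed `i`, \eqn{\sum_j (c_i \cdot c_j)^2 = b/d} — the normalization that
#' makes the time-correlated kernel reproduce a prescribed VACF exactly.
#'
#' @param b Integer number of velocity channels, `b >= 2`.
#'
#' @return An object of class `channel_set`: a list with elements `b`,
#'   `vectors` (a `b x 2` matrix of unit vectors, row `j + 1` is `c_j`) and
#'   `d` (effective spatial dimension).
#'
#' @examples
#' ch <- channel_set(4)   # 2D square lattice
#' ch$vectors
#' channel_set(6)$d       # hexagonal lattice, d = 2
#' @export
channel_set <- function(b) {
  if (length(b) != 1L || !is.finite(b) || b != round(b) || b < 2) {
    stop("invalid lattice geometry: `b` must be a single integer >= 2",
         call. = FALSE)
  }
  b <- as.integer(b)
  j <- seq_len(b) - 1L
  theta <- 2 * pi * j / b
  vectors <- cbind(cos(theta), sin(theta))
  # clean exact zeros (cos(pi/2) etc. carry ~1e-16 noise)
  vectors[abs(vectors) < 1e-15] <- 0
  structure(
    list(b = b, vectors = vectors, d = if (b == 2L) 1L else 2L),
    class = "channel_set"
  )
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> b = %d velocity channels, d = %d\n", x$b, x$d))
  invisible(x)
}

#' Pairwise channel alignments
#'
#' Precomputes the `b x b` table of dot products \eqn{c_i \cdot c_j}.  Because
#' the channels are equally spaced on the unit circle the table is circulant:
#' entry `(i, j)` is `cos(2 pi (i - j) / b)`, so every row is the first row
#' rotated.  All four reorientation kernels and the VACF estimator consume
#' this table.
#'
#' @param set A [channel_set()].
#' @return A symmetric `b x b` numeric matrix with unit diagonal.
#' @examples
#' alignment_matrix(channel_set(4))[1, ]   # 1, 0, -1, 0
#' @export
alignment_matrix <- function(set) {
  stopifnot(inherits(set, "channel_set"))
  m <- tcrossprod(set$vectors)
  m[abs(m) < 1e-15] <- 0
  m
}

#' Physical scales of the lattice walk
#'
#' The walk has two microscopic scales, the lattice spacing `epsilon` and the
#' step duration `tau`, or equivalently two macroscopic ones: the
#' instantaneous speed `v = epsilon / tau` and the random-walk diffusion
#' coefficient `D_rw = epsilon^2 / (2 d tau)`.  Given `(v, D_rw, d)` the
#' microscopic pair is uniquely `epsilon = 2 d D_rw / v`,
#' `tau = 2 d D_rw / v^2`; this is how simulation scales are specified
#' throughout (e.g. `v = 16`, `D_rw = 1` on the square lattice gives
#' `epsilon = 0.25`, `tau = 0.015625`).
#'
#' @param v Instantaneous walker speed (length / time), `> 0`.
#' @param D_rw Random-walk diffusion coefficient (length^2 / time), `> 0`.
#' @param d Effective spatial dimension (1 or 2), usually `set$d`.
#' @return An object of class `lattice_scales`: list with `epsilon`, `tau`,
#'   `v`, `D_rw`, `d`.
#' @examples
#' sc <- lattice_scales(v = 16, D_rw = 1, d = 2)
#' sc$epsilon  # 0.25
#' sc$tau      # 0.015625
#' @export
lattice_scales <- function(v, D_rw, d = 2) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v), v > 0,
            is.numeric(D_rw), length(D_rw) == 1L, is.finite(D_rw), D_rw > 0,
            d %in% c(1, 2))
  epsilon <- 2 * d * D_rw / v
  tau <- 2 * d * D_rw / v^2
  structure(
    list(epsilon = epsilon, tau = tau, v = v, D_rw = D_rw, d = as.integer(d)),
    class = "lattice_scales"
  )
}

#' @export
print.lattice_scales <- function(x, ...) {
  cat(sprintf(
    "<lattice_scales> v = %g, D_rw = %g, d = %d  (epsilon = %g, tau = %g)\n",
    x$v, x$D_rw, x$d, x$epsilon, x$tau))
  invisible(x)
}
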