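#' Configure an LGCA random-walk model
#'
#' Bundles the model kind with exactly the parameters it needs:
#'
#' * `"classical"` — no parameters;
#' * `"persistent"` — `beta` (sensitivity, `>= 0`);
#' * `"time_correlated"` — a [vacf_spec()] (power-law with `Delta <= tau`,
#'   or piecewise-ballistic);
#' * `"generalized"` — a power-law [vacf_spec()] as the maximum-caliber
#'   constraint target.
#'
#' @param model One of `"classical"`, `"persistent"`, `"time_correlated"`,
#'   `"generalized"`.
#' @param channels A [channel_set()].
#' @param scales A [lattice_scales()].
#' @param beta Sensitivity (persistent model only).
#' @param vacf A [vacf_spec()] (time-correlated / generalized models only).
#' @param ballistic_extension Passed to [tc_probabilities()] (time-correlated
#'   model only).
#' @return An object of class `model_config`.
#' @examples
#' model_config("persistent", channel_set(4),
#'              lattice_scales(v = 16, D_rw = 1), beta = 5)
#' @export
model_config <- function(model = c("classical", "persistent",
                                   "time_correlated", "generalized"),
                         channels, scales, beta = NULL, vacf = NULL,
                         ballistic_extension = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(channels, "channel_set"),
            inherits(scales, "lattice_scales"))
  if (model == "persistent") {
    if (is.null(beta) || !is.finite(beta) || beta < 0) {
      stop("persistent model requires a finite sensitivity `beta` >= 0",
           call. = FALSE)
    }
  } else if (!is.null(beta)) {
    stop(sprintf("`beta` is not a parameter of the %s model", model),
         call. = FALSE)
  }
  if (model %in% c("time_correlated", "generalized")) {
    if (!inherits(vacf, "vacf_spec")) {
      stop(sprintf("%s model requires a vacf_spec", model), call. = FALSE)
    }
    if (model == "time_correlated" && vacf$family == "power_law" &&
        vacf$Delta > scales$tau * (1 + 1e-9)) {
      stop("time-correlated model with a bare power-law VACF requires ",
           "Delta <= tau (crossover time not larger than the step length); ",
           "use the piecewise_ballistic family instead", call. = FALSE)
    }
    if (model == "generalized" &&
        !vacf$family %in% c("power_law", "tanh_power_law")) {
      stop("generalized model requires a power-law target vacf_spec",
           call. = FALSE)
    }
  } else if (!is.null(vacf)) {
    stop(sprintf("`vacf` is not a parameter of the %s model", model),
         call. = FALSE)
  }
  structure(list(model = model, channels = channels, scales = scales,
                 beta = beta, vacf = vacf,
                 ballistic_extension = isTRUE(ballistic_extension)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s walk, b = %d, v = %g, D_rw = %g\n",
              x$model, x$channels$b, x$scales$v, x$scales$D_rw))
  if (!is.null(x$beta)) cat(sprintf("  beta = %g\n", x$beta))
  if (!is.null(x$vacf)) { cat("  "); print(x$vacf) }
  invisible(x)
}

#' One inverse-CDF reorientation draw
#'
#' Maps a uniform variate to a channel index by the inverse CDF of the
#' probability vector, in channel-index order.  A variate falling exactly on
#' a CDF boundary goes to the higher index (tie-break convention).  This is
#' the single primitive through which the engine consumes randomness, which
#' makes the sampled trajectories an exact deterministic function of the
#' seed.
#'
#' @param p Probability vector over the `b` channels.
#' @param u Uniform variate(s) in `[0, 1)`.
#' @return Integer channel index (1-based), vectorized over `u`.
#' @examples
#' advance_step(c(0.25, 0.25, 0.25, 0.25), c(0.1, 0.25, 0.9))  # 1, 2, 4
#' @export
advance_step <- function(p, u) {
  p <- validate_probabilities(p)
  b <- length(p)
  boundaries <- cumsum(p)[-b]
  findInterval(u, boundaries) + 1L
}

#' Simulate a seeded ensemble of independent LGCA walkers
#'
#' Each walker starts at the origin with an initial channel drawn uniformly
#' over the `b` channels (or fixed via `initial_channel`, useful for
#' debugging).  At every step `k = 1, ..., n_steps` a new channel is drawn
#' from the model's reorientation kernel — conditioning on the previous
#' channel (classical, persistent) or on the initial channel and `k`
#' (time-correlated, generalized) — and the walker moves by
#' `epsilon * c_channel`.  Walkers never interact: the multi-particle
#' reorientation probability factorizes over particles, so each is simulated
#' on its own copy of the lattice and the exclusion principle is honoured
#' trivially.
#'
#' Sampling is vectorized step-major: at each step one uniform variate per
#' particle is drawn from the single seeded RNG stream, and particles grouped
#' by their conditioning channel map their variates to channels through
#' [advance_step()].  Identical
#' `(config, n_particles, n_steps, seed)` therefore reproduce the channel
#' matrix bit for bit.
#'
#' @param config A [model_config()].
#' @param n_particles Number of walkers, `>= 1`.
#' @param n_steps Number of steps, `>= 1`.
#' @param seed Integer RNG seed; required, so every ensemble is reproducible.
#' @param initial_channel Optional fixed initial channel for all walkers.
#' @return An object of class `trajectory_ensemble`: list with `channels`
#'   (`n_particles x (n_steps + 1)` integer matrix, column `k + 1` holding
#'   the channel at step `k`), `x`, `y` (position matrices in length units,
#'   starting at 0), `config`, `n_particles`, `n_steps`, `seed`, and
#'   `ballistic_extended_steps` (integer vector of steps where the
#'   time-correlated kernel extended the ballistic phase, normally empty).
#'   Use [generics::tidy()] for the long-format tibble.
#' @examples
#' cfg <- model_config("classical", channel_set(4),
#'                     lattice_scales(v = 16, D_rw = 1))
#' ens <- simulate_ensemble(cfg, n_particles = 100, n_steps = 50, seed = 1)
#' ens
#' @export
simulate_ensemble <- function(config, n_particles, n_steps, seed,
                              initial_channel = NULL) {
  stopifnot(inherits(config, "model_config"),
            n_particles >= 1, n_steps >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n_particles <- as.integer(n_particles)
  n_steps <- as.integer(n_steps)
  set <- config$channels
  b <- set$b
  align <- alignment_matrix(set)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  channels <- matrix(0L, nrow = n_particles, ncol = n_steps + 1L)
  channels[, 1L] <- if (is.null(initial_channel)) {
    advance_step(rep(1 / b, b), stats::runif(n_particles))
  } else {
    check_channel(initial_channel, set)
    rep(as.integer(initial_channel), n_particles)
  }

  extended <- integer(0)
  for (k in seq_len(n_steps)) {
    cond <- switch(config$model,
      classical = NULL,
      persistent = channels[, k],
      channels[, 1L])   # time-correlated / generalized condition on i_0
    if (is.null(cond)) {
      channels[, k + 1L] <- advance_step(rep(1 / b, b),
                                         stats::runif(n_particles))
    } else {
      draw <- stats::runif(n_particles)
      nxt <- integer(n_particles)
      for (ch in sort(unique(cond))) {
        idx <- which(cond == ch)
        p <- switch(config$model,
          persistent = persistent_probabilities(set, ch, config$beta),
          time_correlated = tc_probabilities(
            set, ch, k, config$vacf, config$scales,
            ballistic_extension = config$ballistic_extension),
          generalized = gtc_probabilities(set, ch, k, config$vacf,
                                          config$scales))
        if (isTRUE(attr(p, "ballistic_extended"))) {
          extended <- union(extended, k)
        }
        nxt[idx] <- advance_step(p, draw[idx])
      }
      channels[, k + 1L] <- nxt
    }
  }

  eps <- config$scales$epsilon
  # position after step k: eps * cumulative sum of channel vectors over
  # steps 1..k (the initial channel is an orientation, not a displacement)
  step_ch <- channels[, -1L, drop = FALSE]
  x <- cbind(0, eps * rowcumsum(matrix(set$vectors[step_ch, 1L],
                                       nrow = n_particles)))
  y <- cbind(0, eps * rowcumsum(matrix(set$vectors[step_ch, 2L],
                                       nrow = n_particles)))

  structure(list(channels = channels, x = x, y = y, config = config,
                 n_particles = n_particles, n_steps = n_steps,
                 seed = as.integer(seed), align = align,
                 ballistic_extended_steps = sort(extended)),
            class = "trajectory_ensemble")
}

rowcumsum <- function(m) {
  for (j in seq_len(ncol(m))[-1L]) m[, j] <- m[, j - 1L] + m[, j]
  m
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %s walk: %d particles x %d steps (seed %d)\n",
    x$config$model, x$n_particles, x$n_steps, x$seed))
  invisible(x)
}

#' Tidy a trajectory ensemble into a long tibble
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `particle`, `step`, `t`, `channel`, `x`,
#'   `y`, one row per particle per step (step 0 = initial state at the
#'   origin).
#' @method tidy trajectory_ensemble
#' @export
tidy.trajectory_ensemble <- function(x, ...) {
  steps <- 0:x$n_steps
  xs <- as.vector(x$x)
  ys <- as.vector(x$y)
  tibble::tibble(
    particle = rep(seq_len(x$n_particles), times = length(steps)),
    step = rep(steps, each = x$n_particles),
    t = rep(steps * x$config$scales$tau, each = x$n_particles),
    channel = as.vector(x$channels),
    x = xs,
    y = ys
  ) |>
    dplyr::arrange(.data$particle, .data$step)
}
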