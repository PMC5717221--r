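#' Empirical velocity autocorrelation function
#'
#' The VACF estimate at lag `k` is the ensemble mean of the dot product
#' between the orientation at step `k` and the *initial* orientation,
#' \deqn{\hat g(k) = \langle c_{i_0} \cdot c_{i_k} \rangle,}
#' exactly the quantity the time-correlated kernels are constructed to
#' prescribe.  `hat g(0) = 1` with zero standard error by definition.  With
#' `stationary = TRUE` a time-averaged variant is returned instead —
#' per-particle averages of \eqn{c_{i_m} \cdot c_{i_{m+k}}} over all time
#' origins `m` — appropriate only for walks with time-translation-invariant
#' correlations (classical, persistent); it is a different estimand for the
#' initial-orientation-coupled models and is therefore opt-in and labelled
#' in the result metadata.
#'
#' @param ensemble A `trajectory_ensemble` with at least 2 particles.
#' @param stationary Use the time-averaged estimator (default `FALSE`).
#' @return A `curve_series` tibble with columns `k`, `t`, `value`, `sem`
#'   (standard error of the ensemble mean), `n`.
#' @examples
#' cfg <- model_config("persistent", channel_set(4),
#'                     lattice_scales(v = 16, D_rw = 1), beta = 5)
#' ens <- simulate_ensemble(cfg, 500, 50, seed = 2)
#' empirical_vacf(ens)
#' @export
empirical_vacf <- function(ensemble, stationary = FALSE) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (ensemble$n_particles < 2) {
    stop("VACF estimation requires at least 2 particles", call. = FALSE)
  }
  b <- ensemble$config$channels$b
  align <- ensemble$align
  ch <- ensemble$channels
  n <- ensemble$n_particles
  if (!stationary) {
    # dot products c_{i_0} . c_{i_k}: index the circulant alignment table
    dots <- matrix(align[cbind(rep(ch[, 1L], ncol(ch)), as.vector(ch))],
                   nrow = n)
    value <- colMeans(dots)
    sem <- apply(dots, 2L, stats::sd) / sqrt(n)
  } else {
    kmax <- ensemble$n_steps
    value <- numeric(kmax + 1L)
    sem <- numeric(kmax + 1L)
    for (k in 0:kmax) {
      m <- ncol(ch) - k
      lagdots <- matrix(
        align[cbind(as.vector(ch[, seq_len(m), drop = FALSE]),
                    as.vector(ch[, k + seq_len(m), drop = FALSE]))],
        nrow = n)
      per_particle <- rowMeans(lagdots)
      value[k + 1L] <- mean(per_particle)
      sem[k + 1L] <- stats::sd(per_particle) / sqrt(n)
    }
  }
  value[1L] <- 1; sem[1L] <- 0
  new_curve_series(k = 0:ensemble$n_steps,
                   tau = ensemble$config$scales$tau,
                   value = value, sem = sem, n = n,
                   meta = list(kind = "vacf",
                               estimator = if (stationary) "stationary"
                                           else "initial_orientation",
                               model = ensemble$config$model))
}

#' Empirical mean-square displacement
#'
#' Ensemble mean of the squared displacement from the starting position,
#' \eqn{\hat{\langle r_k^2\rangle} = \langle \|x_k - x_0\|^2 \rangle}, with
#' the standard error of the mean per lag.  A single-particle ensemble is
#' accepted but flagged with `sem = NA`.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return A `curve_series` tibble (`k`, `t`, `value`, `sem`, `n`).
#' @export
empirical_msd <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  r2 <- ensemble$x^2 + ensemble$y^2   # start is the origin
  n <- ensemble$n_particles
  value <- colMeans(r2)
  sem <- if (n >= 2) apply(r2, 2L, stats::sd) / sqrt(n) else rep(NA_real_,
                                                                 ncol(r2))
  new_curve_series(k = 0:ensemble$n_steps,
                   tau = ensemble$config$scales$tau,
                   value = value, sem = sem, n = n,
                   meta = list(kind = "msd",
                               model = ensemble$config$model))
}

new_curve_series <- function(k, tau, value, sem, n, meta = list()) {
  out <- tibble::tibble(k = as.integer(k), t = k * tau,
                        value = as.numeric(value), sem = as.numeric(sem),
                        n = as.integer(n))
  class(out) <- c("curve_series", class(out))
  attr(out, "meta") <- meta
  out
}

select_window <- function(series, window, min_lags) {
  s <- series[series$k > 0, , drop = FALSE]
  if (!is.null(window)) {
    if (length(window) != 2L || any(window <= 0) || window[2] <= window[1]) {
      stop("`window` must be c(t_min, t_max) with 0 < t_min < t_max",
           call. = FALSE)
    }
    s <- s[s$t >= window[1] & s$t <= window[2], , drop = FALSE]
  }
  if (nrow(s) < min_lags) {
    stop(sprintf("need at least %d lags in the window (have %d)",
                 min_lags, nrow(s)), call. = FALSE)
  }
  s
}

#' Diffusion coefficient from the MSD slope
#'
#' The diffusion coefficient is defined through the long-time MSD slope,
#' `D = lim <r^2> / (2 d t)`; the estimator is the least-squares slope of
#' the empirical MSD against `t` over the chosen window, divided by `2 d`.
#' A low R-squared of the linear fit flags curves that are not in the linear
#' (normal-diffusion) regime, e.g. ballistic transients.
#'
#' @param msd A `curve_series` from [empirical_msd()] (or any tibble with
#'   `t`, `value`).
#' @param d Spatial dimension used in the normalization.
#' @param window Optional `c(t_min, t_max)` restriction; at least 5 lags.
#' @param r2_threshold Linearity flag threshold on R-squared (default 0.99).
#' @return A `diffusion_fit` object; see [tidy.diffusion_fit()].
#' @export
estimate_diffusion_coefficient <- function(msd, d = 2, window = NULL,
                                           r2_threshold = 0.99) {
  s <- select_window(msd, window, min_lags = 5L)
  fit <- stats::lm(value ~ t, data = s)
  slope <- stats::coef(fit)[["t"]]
  # noiseless input yields an exact fit; the "essentially perfect fit"
  # advisory is expected there
  sfit <- suppressWarnings(summary(fit))
  se <- sfit$coefficients["t", "Std. Error"]
  ci <- suppressWarnings(stats::confint(fit, "t", level = 0.95))
  r2 <- sfit$r.squared
  structure(list(D = slope / (2 * d), se = se / (2 * d),
                 conf.low = ci[1] / (2 * d), conf.high = ci[2] / (2 * d),
                 r_squared = r2, linear = r2 >= r2_threshold,
                 d = d, n_lags = nrow(s), window = range(s$t), fit = fit),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.6g (95%% CI %.6g..%.6g), R^2 = %.4f%s\n",
              x$D, x$conf.low, x$conf.high, x$r_squared,
              if (!x$linear) "  [nonlinear: MSD not in the diffusive regime]"
              else ""))
  invisible(x)
}

#' Classify the diffusion regime of an MSD curve
#'
#' Fits the scaling exponent of `<r^2> ~ t^phi` by ordinary least squares of
#' `log(value)` on `log(t)` and labels the curve `"normal"` if the 95%
#' confidence interval of the exponent contains 1, `"subdiffusive"` below,
#' `"superdiffusive"` above.  CI-based labelling is used rather than a fixed
#' epsilon because the regimes are asymptotic statements.
#'
#' @param msd A `curve_series` (or tibble with `t`, `value`), positive
#'   values in the window.
#' @param window Optional `c(t_min, t_max)`; at least 8 lags.
#' @return A `regime_fit` object with fields `exponent`, `conf.low`,
#'   `conf.high`, `label`, `window`.
#' @examples
#' msd <- tibble::tibble(k = 1:50, t = (1:50) / 10, value = ((1:50) / 10)^1.5)
#' classify_regime(msd)$label   # "superdiffusive"
#' @export
classify_regime <- function(msd, window = NULL) {
  s <- select_window(msd, window, min_lags = 8L)
  if (any(s$value <= 0)) {
    stop("regime classification requires positive MSD values in the window",
         call. = FALSE)
  }
  fit <- stats::lm(log(value) ~ log(t), data = s)
  expo <- stats::coef(fit)[[2]]
  ci <- suppressWarnings(stats::confint(fit, "log(t)", level = 0.95))
  label <- if (ci[1] > 1) "superdiffusive"
           else if (ci[2] < 1) "subdiffusive"
           else "normal"
  structure(list(exponent = expo, conf.low = ci[1], conf.high = ci[2],
                 label = label, window = range(s$t), n_lags = nrow(s),
                 fit = fit),
            class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat(sprintf("<regime_fit> exponent = %.4f (95%% CI %.4f..%.4f): %s\n",
              x$exponent, x$conf.low, x$conf.high, x$label))
  invisible(x)
}

#' Fit a power law to an empirical VACF
#'
#' Estimates the amplitude `A = C0 Delta^phi` and the decay exponent `phi`
#' of `g(t) = A t^{-phi}`.  `C0` and `Delta` are *not* separately
#' identifiable from a single power law (only their combination `A` enters),
#' so they are not reported.
#'
#' The fit is weighted nonlinear least squares on the *linear* scale
#' (weights `1/sem^2` when standard errors are available), started from a
#' log-log regression over the positive lags.  Fitting on the linear scale
#' matters in the low signal-to-noise tail: a log-domain fit must discard
#' non-positive estimates and weight by the noisy estimates themselves,
#' which biases the exponent; the linear-scale fit uses every lag
#' symmetrically.  Lags with zero standard error (deterministic ballistic
#' lags) are excluded.  A lag-1 autocorrelation of the ordered weighted
#' residuals above `resid_acf_threshold` flags residual structure, i.e. a
#' VACF that is not power-law shaped (exponential decay, for instance).
#'
#' @param vacf A `curve_series` from [empirical_vacf()] (or tibble with `t`,
#'   `value` and optionally `sem`); at least 8 usable lags, of which at
#'   least 8 positive.
#' @param window Optional `c(t_min, t_max)` restriction.
#' @param resid_acf_threshold Structure-flag threshold (default 0.5).
#' @return A `vacf_power_fit` object with fields `A`, `phi`, standard errors
#'   and 95% CIs, `structured` (logical diagnostic) and `n_lags`.
#' @export
fit_vacf_power_law <- function(vacf, window = NULL,
                               resid_acf_threshold = 0.5) {
  s <- select_window(vacf, window, min_lags = 1L)
  has_sem <- "sem" %in% names(s) && all(is.finite(s$sem))
  if (has_sem) s <- s[s$sem > 0, , drop = FALSE]
  pos <- s[s$value > 0, , drop = FALSE]
  if (nrow(pos) < 8L) {
    stop("need at least 8 positive VACF lags for a power-law fit; ",
         "non-positive correlations suggest the delta or alternating ",
         "families instead", call. = FALSE)
  }
  w <- if (has_sem) 1 / s$sem^2 else rep(1, nrow(s))
  # starting values from an unweighted log-log regression on positive lags
  start_fit <- stats::lm(log(value) ~ log(t), data = pos)
  start <- list(A = exp(stats::coef(start_fit)[[1]]),
                phi = -stats::coef(start_fit)[[2]])
  fit <- tryCatch(
    stats::nls(value ~ A * t^(-phi), data = s, weights = w, start = start,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate noiseless input (zero residuals): the starting log fit is
    # already exact
    co <- suppressWarnings(summary(start_fit))$coefficients
    est <- c(start$A, start$phi)
    se <- c(start$A * co[1, 2], co[2, 2])
    df <- stats::df.residual(start_fit)
    res <- stats::residuals(start_fit)[order(pos$t)]
    n_used <- nrow(pos)
  } else {
    co <- summary(fit)$coefficients
    est <- co[, 1]
    se <- co[, 2]
    df <- stats::df.residual(fit)
    res <- (stats::residuals(fit) * sqrt(w))[order(s$t)]
    n_used <- nrow(s)
  }
  q <- stats::qt(0.975, df)
  acf1 <- if (length(res) > 2 && stats::sd(res) > 0) {
    stats::cor(res[-1], res[-length(res)])
  } else 0
  structure(list(
    A = est[[1]], A_conf = est[[1]] + c(-1, 1) * q * se[[1]],
    phi = est[[2]], phi_se = se[[2]],
    phi_conf = est[[2]] + c(-1, 1) * q * se[[2]],
    structured = is.finite(acf1) && acf1 > resid_acf_threshold,
    resid_acf1 = acf1, n_lags = n_used, fit = fit %||% start_fit),
    class = "vacf_power_fit")
}

#' @export
print.vacf_power_fit <- function(x, ...) {
  cat(sprintf(
    "<vacf_power_fit> g(t) = A t^-phi: A = %.5g, phi = %.5g (95%% CI %.5g..%.5g)%s\n",
    x$A, x$phi, x$phi_conf[1], x$phi_conf[2],
    if (x$structured) "  [residual structure: power law questionable]"
    else ""))
  invisible(x)
}
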