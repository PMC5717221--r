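test_that("target VACF families evaluate per their definitions", {
  # power law equals C0 at the crossover time
  sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 1)
  expect_equal(evaluate_target_vacf(sp, 0.016)$value, 0.5)
  expect_error(evaluate_target_vacf(sp, 0.001), "t < Delta")

  # piecewise: fully correlated until t* = Delta * C0^(1/phi)
  spp <- vacf_spec("piecewise_ballistic", C0 = 0.5, Delta = 10, phi = 0.2)
  expect_equal(evaluate_target_vacf(spp, 0.2)$value, 1)    # t < t* = 0.3125
  expect_equal(evaluate_target_vacf(spp, 1)$value, 0.5 * 10^0.2)

  # delta family: correlation only at t = 0
  spd <- vacf_spec("delta")
  expect_equal(evaluate_target_vacf(spd, c(0, 0.1, 3))$value, c(1, 0, 0))

  # exponential family
  spe <- vacf_spec("exponential", alpha = -2)
  expect_equal(evaluate_target_vacf(spe, c(0, 1))$value, c(1, exp(-2)))
})

test_that("persistent mode eigenvalue matches the b = 4 closed form", {
  ch <- channel_set(4)
  expect_equal(persistent_mode_eigenvalue(5, ch), tanh(2.5),
               tolerance = 1e-12)
  expect_equal(persistent_mode_eigenvalue(3, ch), tanh(1.5),
               tolerance = 1e-12)
  for (b in c(2, 3, 4, 6, 8)) {
    expect_equal(persistent_mode_eigenvalue(0, channel_set(b)), 0,
                 tolerance = 1e-12)
  }
  # direct 4-term enumeration oracle
  a <- c(1, 0, -1, 0)
  for (beta in c(0.5, 2, 7)) {
    w <- exp(beta * a)
    expect_equal(persistent_mode_eigenvalue(beta, ch), sum(a * w) / sum(w))
  }
})

test_that("persistent VACF: continuum form equals lambda1^k at discrete times", {
  ch <- channel_set(4)
  for (pars in list(c(5, 16, 1), c(3, 16, 1), c(2, 4, 0.5))) {
    beta <- pars[1]
    sc <- lattice_scales(v = pars[2], D_rw = pars[3])
    k <- c(0:5, 50)
    g <- vacf_persistent(k * sc$tau, beta, ch, sc)$value
    expect_equal(g, tanh(beta / 2)^k, tolerance = 1e-12)
  }
  # arithmetic check of the cited closed forms at t = 1
  sc <- ref_scales
  expect_equal(vacf_persistent(1, 5, ch, sc)$value,
               exp(64 * log(tanh(2.5))), tolerance = 1e-12)
  expect_equal(vacf_persistent(1, 5, ch, sc)$value, 0.422118,
               tolerance = 1e-6)
  expect_equal(vacf_persistent(0, 5, ch, sc)$value, 1)
  expect_error(vacf_persistent(1, 0, ch, sc), "eigenvalue")
})

test_that("generalized VACF is the tanh of the target with power-law tail", {
  sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 0.3)
  expect_equal(vacf_generalized(0.016, sp)$value, tanh(0.5),
               tolerance = 1e-12)
  expect_equal(vacf_generalized(0.016, sp)$value, 0.46212, tolerance = 1e-5)
  # C0 -> 0: vanishes
  sp0 <- vacf_spec("power_law", C0 = 1e-12, Delta = 0.016, phi = 0.3)
  expect_true(all(abs(vacf_generalized(c(0.1, 1), sp0)$value) < 1e-12))
  # long-time agreement with the bare target to second order
  tbig <- 0.016 * (1e6)^(1 / 0.3)   # (Delta/t)^phi = 1e-6
  expect_equal(vacf_generalized(tbig, sp)$value / (0.5 * 1e-6), 1,
               tolerance = 1e-12)
  # general-b route agrees with the square-lattice tanh form
  expect_equal(vacf_generalized(c(0.05, 0.5), sp, set = channel_set(4))$value,
               tanh(0.5 * (0.016 / c(0.05, 0.5))^0.3), tolerance = 1e-12)
})

test_that("generalized VACF tail exponent", {
  expect_equal(generalized_tail_exponent(0.5, 0.2), 0.2 / sinh(1),
               tolerance = 1e-12)
  expect_equal(generalized_tail_exponent(0.5, 0.2), 0.17018,
               tolerance = 1e-4)
  expect_equal(generalized_tail_exponent(0, 0.2), 0.2)
  expect_equal(generalized_tail_exponent(1e-9, 0.2), 0.2, tolerance = 1e-6)
  for (C0 in c(0.1, 0.5, 2)) {
    for (phi in c(0.1, 1, 3)) {
      expect_gt(generalized_tail_exponent(C0, phi), 0)
    }
  }
})

test_that("classical MSD is linear with the discrete form k epsilon^2", {
  sc <- ref_scales
  expect_equal(msd_classical(10, sc)$value, 40)
  expect_equal(msd_classical(0, sc)$value, 0)
  sc1 <- lattice_scales(v = 1, D_rw = 0.25)  # epsilon = 1, tau = 1
  expect_equal(msd_classical(100 * sc1$tau, sc1)$value, 100)
})

test_that("persistent MSD: small-t expansion, classical limit, discrete consistency", {
  ch <- channel_set(4)
  sc <- ref_scales
  # t -> 0 series: 2 d D t + v^2 t^2 + O(t^3)
  tt <- 1e-5
  lead <- 2 * 2 * 1 * tt + 256 * tt^2
  expect_equal(msd_persistent(tt, 5, ch, sc)$value, lead, tolerance = 1e-4)
  # beta -> 0 (alpha = ln tanh(beta/2) -> -infty): approaches the classical
  # line 2 d D t; the approach is logarithmic in beta, so check monotone
  # convergence over decades rather than a tight limit
  ratios <- vapply(c(1e-2, 1e-6, 1e-12),
                   function(bta) msd_persistent(5, bta, ch, sc)$value / 20,
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_equal(ratios[3], 1, tolerance = 0.08)
  # Eq-13-style discrete sum from an independent direct implementation
  lam <- tanh(1.5)
  k <- 40
  direct <- 2 * 2 * 1 * k * sc$tau +
    2 * sc$v^2 * sum((k * sc$tau - (1:k) * sc$tau) * lam^(1:k)) * sc$tau
  expect_equal(msd_persistent_discrete(k, 3, ch, sc)$value, direct,
               tolerance = 1e-12)
  expect_error(msd_persistent(1, 0, ch, sc))
})

test_that("discrete and continuum persistent MSD converge as tau -> 0 at fixed continuum VACF", {
  # hold the continuum decay rate A = alpha / tau fixed (the limit in which
  # the continuum expressions are derived) and shrink tau by factors of 10
  ch <- channel_set(4)
  A <- log(tanh(1.5)) / ref_scales$tau
  tg <- c(0.5, 1, 2)
  err <- vapply(c(1, sqrt(10), 10), function(f) {
    sc <- lattice_scales(v = 16 * f, D_rw = 1)
    beta_eq <- 2 * atanh(exp(A * sc$tau))
    k <- round(tg / sc$tau)
    d13 <- msd_persistent_discrete(k, beta_eq, ch, sc)$value
    e15 <- msd_persistent(k * sc$tau, beta_eq, ch, sc)$value
    max(abs(d13 - e15) / e15)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 50)   # ~ O(tau) convergence
})

test_that("discrete TGK formula matches hand evaluation and limits", {
  # hand-evaluated example: k = 2, tau = 1, v = 1, d = 2, D = 1/4,
  # g = (0.5, 0.25) -> 1.375 + 0.875 = 2.25
  sc <- lattice_scales(v = 1, D_rw = 0.25)
  expect_equal(msd_independent_discrete(2, c(0.5, 0.25), sc)$value, 2.25)
  # g = 0: classical
  expect_equal(msd_independent_discrete(10, rep(0, 10), sc)$value,
               2 * 2 * 0.25 * 10 * 1)
  # g = 1: ballistic, (v k tau)^2 exactly (the diffusive term cancels)
  k <- 0:20
  expect_equal(msd_independent_discrete(k, rep(1, 20), sc)$value,
               (1 * k * 1)^2)
})

test_that("every closed-form MSD agrees with the quadrature oracle", {
  sc <- ref_scales
  ch <- channel_set(4)
  ts <- 10^seq(log10(2 * 0.016), 2, length.out = 20)

  # time-correlated family, including the marginal exponents
  for (phi in c(0.2, 0.5, 1, 1.5, 2)) {
    sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = phi)
    g <- function(s) 0.5 * (0.016 / s)^phi
    or <- msd_numeric_oracle(g, ts, sc, lower_limit = 0.016,
                             form = "independent")
    expect_equal(msd_tc(ts, sp, sc)$value, or, tolerance = 1e-6)
  }

  # persistent closed form vs stationary oracle with exponential VACF
  A <- log(tanh(2.5)) / sc$tau
  or <- msd_numeric_oracle(function(s) exp(A * s), ts, sc,
                           lower_limit = 0, form = "stationary")
  expect_equal(msd_persistent(ts, 5, ch, sc)$value, or, tolerance = 1e-6)

  # stationary generalized closed forms vs linearized stationary oracle
  for (phi in c(0.5, 1, 1.3, 2, 3)) {
    sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = phi)
    g <- function(s) 0.5 * (0.016 / s)^phi
    or <- msd_numeric_oracle(g, ts, sc, lower_limit = 0.016,
                             form = "stationary")
    expect_equal(msd_gtc_stationary(ts, sp, sc)$value, or,
                 tolerance = 1e-6)
  }

  # trivial oracle checks
  expect_equal(msd_numeric_oracle(function(s) 0 * s, 2, sc,
                                  lower_limit = 0, form = "stationary"), 8)
  expect_equal(msd_numeric_oracle(function(s) 0 * s, 2, sc,
                                  lower_limit = 0, form = "independent"), 8)
})

test_that("closed forms are continuous across the marginal exponents", {
  sc <- ref_scales
  ts <- 10^seq(log10(0.05), 2, length.out = 7)
  for (phi_m in c(0.5, 1)) {
    mid <- msd_tc(ts, vacf_spec("power_law", C0 = 0.5, Delta = 0.016,
                                phi = phi_m), sc)$value
    lo <- msd_tc(ts, vacf_spec("power_law", C0 = 0.5, Delta = 0.016,
                               phi = phi_m - 1e-6), sc)$value
    hi <- msd_tc(ts, vacf_spec("power_law", C0 = 0.5, Delta = 0.016,
                               phi = phi_m + 1e-6), sc)$value
    expect_equal(lo / mid, rep(1, length(ts)), tolerance = 1e-4)
    expect_equal(hi / mid, rep(1, length(ts)), tolerance = 1e-4)
  }
  for (phi_m in c(1, 2)) {
    mid <- msd_gtc_stationary(ts, vacf_spec("power_law", C0 = 0.5,
                                            Delta = 0.016, phi = phi_m),
                              sc)$value
    lo <- msd_gtc_stationary(ts, vacf_spec("power_law", C0 = 0.5,
                                           Delta = 0.016,
                                           phi = phi_m - 1e-6), sc)$value
    hi <- msd_gtc_stationary(ts, vacf_spec("power_law", C0 = 0.5,
                                           Delta = 0.016,
                                           phi = phi_m + 1e-6), sc)$value
    expect_equal(lo / mid, rep(1, length(ts)), tolerance = 1e-4)
    expect_equal(hi / mid, rep(1, length(ts)), tolerance = 1e-4)
  }
})

test_that("memory -> 0 limits recover normal diffusion in every model", {
  sc <- ref_scales
  ts <- c(0.5, 2, 10)
  lin <- 2 * 2 * 1 * ts
  sp0 <- vacf_spec("power_law", C0 = 1e-8, Delta = 0.016, phi = 0.7)
  expect_equal(msd_tc(ts, sp0, sc)$value, lin, tolerance = 1e-6)
  expect_equal(msd_gtc_stationary(ts, sp0, sc)$value, lin, tolerance = 1e-6)
  expect_equal(msd_gtc(ts, sp0, sc)$value, lin, tolerance = 1e-6)
})

test_that("piecewise MSD is ballistic then continuous at t*", {
  sc <- lattice_scales(v = 1, D_rw = 0.0125)   # tau = 0.05
  sp <- vacf_spec("piecewise_ballistic", C0 = 0.5, Delta = 10, phi = 0.2)
  ts <- sp$t_star
  expect_equal(msd_tc(ts / 2, sp, sc)$value, (1 * ts / 2)^2)
  # continuity at the ballistic/diffusive junction
  expect_equal(msd_tc(ts * (1 + 1e-9), sp, sc)$value, (1 * ts)^2,
               tolerance = 1e-6)
  # monotone growth after t*
  vals <- msd_tc(ts * c(1.5, 3, 10), sp, sc)$value
  expect_true(all(diff(vals) > 0))
})

test_that("regime taxonomy: long-time log-log slopes of the closed forms", {
  sc <- ref_scales
  Delta <- 0.016
  tgrid <- 10^seq(log10(1e4 * Delta), log10(1e6 * Delta), length.out = 30)
  slope_of <- function(values) {
    s <- loglog_slope(tgrid, values)$slope
    s[length(s)]
  }
  # time-correlated: slope 2(1 - phi) for phi < 1/2, 1 for phi > 1/2
  sp02 <- vacf_spec("power_law", C0 = 0.5, Delta = Delta, phi = 0.2)
  expect_equal(slope_of(msd_tc(tgrid, sp02, sc)$value), 1.6,
               tolerance = 0.02)
  sp15 <- vacf_spec("power_law", C0 = 0.5, Delta = Delta, phi = 1.5)
  expect_equal(slope_of(msd_tc(tgrid, sp15, sc)$value), 1,
               tolerance = 0.02)
  # stationary generalized: slope 2 - phi for phi < 1, 1 for phi > 1
  sp05 <- vacf_spec("power_law", C0 = 0.5, Delta = Delta, phi = 0.5)
  expect_equal(slope_of(msd_gtc_stationary(tgrid, sp05, sc)$value), 1.5,
               tolerance = 0.02)
  sp30 <- vacf_spec("power_law", C0 = 0.5, Delta = Delta, phi = 3)
  expect_equal(slope_of(msd_gtc_stationary(tgrid, sp30, sc)$value), 1,
               tolerance = 0.02)
  # phi = 3: the nonlinear remainder of the expanded form stays bounded
  rem <- gtc_stationary_remainder(10^seq(2, 6, length.out = 20),
                                  sp30, sc)$value
  expect_true(all(abs(rem) <= abs(rem[1]) + 1e-9))
})

test_that("regime boundaries are recovered by bisection on phi", {
  sc <- ref_scales
  expect_equal(regime_boundary_tc(0.5, 0.016, sc), 1, tolerance = 2e-3)
  expect_equal(regime_boundary_gtc_superdiffusion(0.5, 0.016, sc), 1,
               tolerance = 2e-3)
  expect_equal(regime_boundary_gtc_normal(0.5, 0.016, sc), 2,
               tolerance = 2e-3)
})

test_that("square-lattice-specific forms reject other geometries", {
  sp <- vacf_spec("power_law", C0 = 0.5, Delta = 0.016, phi = 0.5)
  expect_error(msd_gtc(1, sp, ref_scales, set = channel_set(6)),
               "square")
  expect_error(msd_gtc_stationary(1, sp, ref_scales, set = channel_set(6)),
               "square")
})
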