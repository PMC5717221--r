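test_that("classical kernel is uniform for any b", {
  expect_equal(classical_probabilities(channel_set(4)), rep(0.25, 4))
  expect_equal(classical_probabilities(channel_set(2)), c(0.5, 0.5))
  p6 <- classical_probabilities(channel_set(6))
  expect_equal(p6, rep(1 / 6, 6))
  expect_equal(sum(p6), 1)
})

test_that("persistent kernel matches the Boltzmann-weight enumeration", {
  ch <- channel_set(4)
  # beta = 5, previous channel 1: weights exp(5), exp(0), exp(-5), exp(0)
  p <- persistent_probabilities(ch, prev_channel = 1, beta = 5)
  Z <- 2 * (1 + cosh(5))
  expect_equal(Z, 150.4199, tolerance = 1e-6)
  expect_equal(p, c(exp(5), 1, exp(-5), 1) / Z, tolerance = 1e-12)
  expect_equal(p[1], 0.98666, tolerance = 1e-4)
  # realized first moment = tanh(beta / 2)
  a <- alignment_matrix(ch)[1, ]
  expect_equal(sum(p * a), tanh(2.5), tolerance = 1e-12)
  expect_equal(sum(p * a), persistent_mode_eigenvalue(5, ch))

  # beta = 0 reduces to the classical kernel for every b
  for (b in c(2, 3, 4, 6, 8)) {
    expect_equal(persistent_probabilities(channel_set(b), 1, 0),
                 classical_probabilities(channel_set(b)))
  }
  expect_error(persistent_probabilities(ch, 1, Inf), "beta")
  expect_error(persistent_probabilities(ch, 5, 1), "channel index")
})

test_that("time-correlated kernel reproduces the prescribed first moment exactly", {
  ch <- channel_set(4)
  sc <- ref_scales
  # g(k tau) = 0.3 via C0 = 0.3, Delta = tau: hand substitution gives
  # (1 + 2 * a_i * 0.3) / 4
  sp <- vacf_spec("power_law", C0 = 0.3, Delta = sc$tau, phi = 0.5)
  p <- tc_probabilities(ch, 1, k = 1, spec = sp, scales = sc)
  expect_equal(p, c(0.40, 0.25, 0.10, 0.25), tolerance = 1e-12)
  expect_equal(sum(p * alignment_matrix(ch)[1, ]), 0.3, tolerance = 1e-15)

  # memoryless limit: g -> 0 at large k gives the uniform kernel
  sp0 <- vacf_spec("power_law", C0 = 1e-14, Delta = sc$tau, phi = 0.5)
  expect_equal(tc_probabilities(ch, 2, 5, sp0, sc), rep(0.25, 4),
               tolerance = 1e-12)

  # |g| > 1/d yields a negative entry: validity error naming the step...
  spbad <- vacf_spec("power_law", C0 = 0.6, Delta = sc$tau, phi = 0.5)
  expect_error(tc_probabilities(ch, 1, 1, spbad, sc), "k = 1")
  # ...unless the ballistic extension is opted into
  pext <- tc_probabilities(ch, 3, 1, spbad, sc, ballistic_extension = TRUE)
  expect_equal(as.numeric(pext), c(0, 0, 1, 0))
  expect_true(attr(pext, "ballistic_extended"))

  # bare power law with Delta > tau is rejected
  splate <- vacf_spec("power_law", C0 = 0.5, Delta = 1, phi = 0.5)
  expect_error(tc_probabilities(ch, 1, 1, splate, sc), "Delta <= tau")
})

test_that("piecewise kernel is degenerate through the ballistic phase", {
  ch <- channel_set(4)
  # C0 = 0.5, Delta = 10, phi = 0.2 -> t* = 10 * 0.5^5 = 0.3125; with
  # tau = 0.05 the ballistic phase lasts ceiling(t*/tau) = 7 steps
  sp <- vacf_spec("piecewise_ballistic", C0 = 0.5, Delta = 10, phi = 0.2)
  expect_equal(sp$t_star, 0.3125)
  expect_equal(ballistic_steps(sp, tau = 0.05), 7L)
  sc <- lattice_scales(v = 1, D_rw = 0.0125)   # tau = 2 d D / v^2 = 0.05
  expect_equal(sc$tau, 0.05)
  for (k in 1:7) {
    expect_equal(tc_probabilities(ch, 2, k, sp, sc), c(0, 1, 0, 0))
  }
  # immediately after the ballistic phase g is still in (1/d, 1): the
  # documented invalid window of the linear kernel
  expect_error(tc_probabilities(ch, 2, 8, sp, sc), "k = 8")
  # once g has decayed to 1/d the kernel is valid and the first-moment
  # identity holds exactly (t = 12.5, g = 0.5 * 0.8^0.2)
  p <- tc_probabilities(ch, 2, 250, sp, sc)
  g250 <- 0.5 * (10 / (250 * 0.05))^0.2
  expect_equal(sum(p * alignment_matrix(ch)[2, ]), g250, tolerance = 1e-12)
})

test_that("generalized kernel is a valid distribution with tanh first moment", {
  ch <- channel_set(4)
  sc <- ref_scales
  # g_target(k tau) = 0.5 => beta(k) = 1, z = 2(1 + cosh 1)
  sp <- vacf_spec("power_law", C0 = 0.5, Delta = sc$tau, phi = 0.5)
  p <- gtc_probabilities(ch, 1, 1, sp, sc)
  z <- 2 * (1 + cosh(1))
  expect_equal(z, 5.08616, tolerance = 1e-5)
  expect_equal(p, c(exp(1), 1, exp(-1), 1) / z, tolerance = 1e-12)
  expect_equal(sum(p * alignment_matrix(ch)[1, ]), tanh(0.5),
               tolerance = 1e-12)

  # no validity error even where the target exceeds 1/d (t << Delta)
  spbig <- vacf_spec("power_law", C0 = 0.9, Delta = 1, phi = 2)
  pbig <- gtc_probabilities(ch, 1, 1, spbig, sc)
  expect_true(all(pbig >= 0))
  expect_equal(sum(pbig), 1, tolerance = 1e-12)
})

test_that("all kernels sum to one over randomized parameter sweeps", {
  set.seed(4021)
  for (rep in 1:50) {
    b <- sample(c(2, 3, 4, 6, 8), 1)
    ch <- channel_set(b)
    sc <- lattice_scales(v = runif(1, 1, 30), D_rw = runif(1, 0.1, 5),
                         d = ch$d)
    i0 <- sample(b, 1)
    k <- sample(1:50, 1)
    beta <- runif(1, 0, 8)
    C0 <- runif(1, -0.4, 0.4) / ch$d + 1e-3
    sp <- vacf_spec("power_law", C0 = C0, Delta = sc$tau,
                    phi = runif(1, 0.05, 2))
    probs <- list(
      classical_probabilities(ch),
      persistent_probabilities(ch, i0, beta),
      tc_probabilities(ch, i0, k, sp, sc),
      gtc_probabilities(ch, i0, k, sp, sc))
    for (p in probs) {
      expect_true(abs(sum(p) - 1) < 1e-12)
      expect_true(all(p >= 0))
    }
    # the defining construction: tc first moment equals g(k tau) exactly
    # (absolute tolerance: the moment itself can be arbitrarily small)
    gk <- C0 * (sc$tau / (k * sc$tau))^sp$phi
    expect_lt(abs(sum(probs[[3]] * alignment_matrix(ch)[i0, ]) - gk),
              1e-12)
    # gtc first moment equals the mode eigenvalue at beta(k) = d g(k)
    # (for negative multipliers use even b, where negating beta flips the
    # moment's sign by the antipodal symmetry of the channel set)
    bk <- ch$d * gk
    if (bk >= 0) {
      expect_lt(abs(sum(probs[[4]] * alignment_matrix(ch)[i0, ]) -
                      persistent_mode_eigenvalue(bk, ch)), 1e-12)
    } else if (b %% 2 == 0) {
      expect_lt(abs(sum(probs[[4]] * alignment_matrix(ch)[i0, ]) +
                      persistent_mode_eigenvalue(-bk, ch)), 1e-12)
    }
  }
})

test_that("probability validation clips noise and rejects bad vectors", {
  expect_equal(validate_probabilities(rep(0.25, 4)), rep(0.25, 4))
  expect_equal(validate_probabilities(c(0.4, 0.25, 0.1, 0.25)),
               c(0.4, 0.25, 0.1, 0.25))
  p <- validate_probabilities(c(0.5, 0.5 + 4e-13, -4e-13))
  expect_equal(p[3], 0)
  expect_error(validate_probabilities(c(0.5, 0.6, -0.1, 0)), "invalid")
  expect_error(validate_probabilities(c(0.5, 0.4)), "sum")
})
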