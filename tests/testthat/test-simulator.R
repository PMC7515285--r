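test_that("Bernoulli train generation is correct and reproducible", {
  expect_true(all(unclass(generate_bernoulli_train(0, 100, seed = 1)) == 0))
  expect_true(all(unclass(generate_bernoulli_train(1, 100, seed = 1)) == 1))
  n <- 1e5
  x <- generate_bernoulli_train(0.3, n, seed = 42)
  expect_lt(abs(mean(unclass(x)) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # fixed seed: bit-identical; and the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  x2 <- generate_bernoulli_train(0.3, n, seed = 42)
  set.seed(99); after <- runif(1)
  expect_identical(unclass(x), unclass(x2))
  expect_identical(before, after)
  expect_error(generate_bernoulli_train(0.3, 0), "positive count")
})

test_that("inhomogeneous generation follows the clipped sinusoidal rate", {
  # zero amplitude reduces to the homogeneous generator statistically
  sig0 <- rate_signal(baseline = 0.3, amplitude = 0, frequency = 1,
                      bin_width = 1, n_bins = 1e5)
  x <- generate_inhomogeneous_train(sig0, seed = 7)
  expect_lt(abs(mean(unclass(x)) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  # clipping: programmed probabilities never exceed [0, 1]
  sig_hi <- rate_signal(baseline = 0.9, amplitude = 0.5, frequency = 1,
                        bin_width = 1, n_bins = 4000)
  prof <- rate_profile(sig_hi)
  expect_true(all(prof >= 0 & prof <= 1))
  expect_equal(max(prof), 1) # the peak really is clipped
  # trial-averaged rate tracks the sinusoid bin by bin
  sig <- rate_signal(baseline = 0.3, amplitude = 0.15, frequency = 1,
                     bin_width = 1, n_bins = 2000)
  prof_hat <- estimate_rate_profile(sig, n_trials = 1000, seed = 8)
  se <- sqrt(prof_hat$alpha_true * (1 - prof_hat$alpha_true) / 1000)
  rms <- sqrt(mean((prof_hat$alpha_hat - prof_hat$alpha_true)^2))
  expect_lt(rms, 3 * mean(se))
})

test_that("two-state release follows the state set by the previous input", {
  # noiseless parameters copy the input through
  noiseless <- synapse_params(1, 0, 1, 0, 0, 0)
  x <- generate_bernoulli_train(0.4, 5000, seed = 11)
  y <- simulate_two_state_release(x, noiseless, seed = 12)
  expect_identical(as.integer(y), as.integer(x))
  # all-zero input never leaves the baseline state
  par <- ref_params(u = 0.9, v = 0.9)
  x0 <- binary_train(rep(0L, 1e5), role = "input")
  y0 <- simulate_two_state_release(x0, par, seed = 13)
  expect_lt(abs(mean(unclass(y0)) - 0.05), 3 * sqrt(0.05 * 0.95 / 1e5))
  expect_error(simulate_two_state_release(y0, par), "role")
})

test_that("two-state simulation without facilitation is the memoryless channel", {
  par0 <- ref_params(u = 0, v = 0)
  n <- 1e6
  x <- generate_bernoulli_train(0.3, n, seed = 21)
  y <- simulate_two_state_release(x, par0, seed = 22)
  xs <- unclass(x); ys <- unclass(y)
  # empirical joint (X, Y) frequencies vs the product channel law
  for (xv in 0:1) for (yv in 0:1) {
    px <- if (xv == 1) 0.3 else 0.7
    py_x <- if (xv == 1) {
      if (yv == 1) 0.5 else 0.5
    } else {
      if (yv == 1) 0.05 else 0.95
    }
    pj <- px * py_x
    emp <- mean(xs == xv & ys == yv)
    expect_lt(abs(emp - pj), 4 * sqrt(pj * (1 - pj) / n))
  }
})

test_that("general model trajectory stays in bounds and has the right limits", {
  par <- ref_params(u = 0.5, v = 0.5)
  gpar <- general_model_params(par, tau_L_p = 250, tau_L_q = 250,
                               tau_f_p = 20, tau_f_q = 20, bin_width = 1)
  # all-zero input: no facilitation ever
  x0 <- binary_train(rep(0L, 5e4), role = "input", bin_width = 1)
  st0 <- general_release_probs(x0, gpar)
  expect_true(all(st0$p == 0.5) && all(st0$p_L == 0.5))
  expect_true(all(st0$q == 0.05) && all(st0$q_L == 0.05))
  y0 <- simulate_general_release(x0, gpar, seed = 31)
  expect_lt(abs(mean(unclass(y0)) - 0.05), 3 * sqrt(0.05 * 0.95 / 5e4))
  # driven trajectory: probabilities confined to [baseline, ceiling]
  x <- generate_bernoulli_train(0.3, 1e5, seed = 32, bin_width = 1)
  st <- general_release_probs(x, gpar)
  expect_true(all(st$p >= 0.5 - 1e-12 & st$p <= 1 + 1e-12))
  expect_true(all(st$p_L >= 0.5 - 1e-12 & st$p_L <= 1 + 1e-12))
  expect_true(all(st$q >= 0.05 - 1e-12 & st$q <= 0.2 + 1e-12))
  expect_true(all(st$q_L >= 0.05 - 1e-12 & st$q_L <= 0.2 + 1e-12))
  # mismatched bin widths are rejected
  x_bad <- binary_train(rep(0L, 100), role = "input", bin_width = 2)
  expect_error(general_release_probs(x_bad, gpar), "bin width")
})

test_that("general model without facilitation matches the memoryless channel", {
  par0 <- ref_params(u = 0, v = 0)
  gpar <- general_model_params(par0, bin_width = 1)
  x <- generate_bernoulli_train(0.3, 2e5, seed = 33, bin_width = 1)
  y <- simulate_general_release(x, gpar, seed = 34)
  est <- plugin_mi(unclass(x), unclass(y))
  expect_lt(abs(est - single_state_rate(0.5, 0.05, 0.3)), 3 / sqrt(2e5))
})

test_that("exponential relaxation is invariant to splitting a bin in two", {
  par <- ref_params(u = 0.5, v = 0.5)
  # a quiescent stretch: propagating 2 ms in one bin equals two 1 ms bins
  g1 <- general_model_params(par, bin_width = 1)
  g2 <- general_model_params(par, bin_width = 2)
  # spike at bin 1, then quiet; compare state at matched times
  x1 <- binary_train(c(1L, rep(0L, 40)), role = "input", bin_width = 1)
  x2 <- binary_train(c(1L, rep(0L, 20)), role = "input", bin_width = 2)
  st1 <- general_release_probs(x1, g1)
  st2 <- general_release_probs(x2, g2)
  # after the jump both grids see the same decay law for p_L
  expect_equal(st1$p_L[seq(2, 41, by = 2)], st2$p_L[2:21], tolerance = 1e-12)
})
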