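test_that("sweep grids validate their axes and points", {
  g <- sweep_grid(axes = list(alpha = c(0.1, 0.3), u = c(0.2, 0.8)),
                  fixed = list(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2),
                  tie = c(v = "u"))
  expect_equal(nrow(g), 4)
  expect_equal(g$v, g$u)
  expect_error(sweep_grid(axes = list(zeta = 1)), "unknown parameter")
  expect_error(sweep_grid(axes = list(u = 0.1), fixed = list(u = 0.2)),
               "both an axis and fixed")
  expect_error(sweep_grid(axes = list(u = 0.1)), "does not define")
  # an invalid point is reported with its coordinates
  bad <- sweep_grid(axes = list(p1 = 0.9),
                    fixed = list(q1 = 0.05, pmax = 0.5, qmax = 0.2,
                                 u = 0.5, v = 0.5, alpha = 0.3))
  expect_error(sweep_bounds(bad), "invalid grid point")
})

test_that("bound sweeps reproduce the analytic collapse and monotonicity", {
  # u = v = 0 grid: all three rate columns coincide
  g0 <- sweep_grid(axes = list(alpha = seq(0.05, 0.95, by = 0.1)),
                   fixed = list(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2,
                                u = 0, v = 0))
  t0 <- sweep_bounds(g0)
  expect_equal(t0$RLB, t0$R1, tolerance = 1e-12)
  expect_equal(t0$RUB, t0$R1, tolerance = 1e-12)
  # reference sweep: RLB strictly increases with u = v at every alpha
  g <- sweep_grid(axes = list(u = c(0.2, 0.5, 0.8),
                              alpha = seq(0.05, 0.95, by = 0.05)),
                  fixed = list(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2),
                  tie = c(v = "u"))
  tab <- sweep_bounds(g)
  for (a in unique(tab$alpha)) {
    sub <- tab[tab$alpha == a, ]
    expect_true(all(diff(sub$RLB[order(sub$u)]) > 0))
  }
  # every analytic cell recomputable from the bounds layer directly
  i <- which(tab$u == 0.5 & tab$alpha == 0.3)
  expect_equal(tab$RUB[i], upper_bound(ref_params(0.5, 0.5), 0.3))
})

test_that("effect maps recover the expected parameter regimes", {
  g <- sweep_grid(axes = list(u = seq(0.05, 0.95, by = 0.09),
                              p1 = seq(0.05, 0.95, by = 0.09)),
                  fixed = list(q1 = 0.05, v = 0.5, pmax = 1, qmax = 0.2,
                               alpha = 0.3))
  m <- effect_map(g)
  pick <- function(p1v, uv) m[abs(m$p1 - p1v) < 1e-9 & abs(m$u - uv) < 1e-9, ]
  # unreliable synapse, strong synchronous facilitation: both rates rise
  lo <- pick(0.05, 0.95)
  expect_equal(as.character(lo$rate_effect), "increases")
  expect_equal(as.character(lo$energy_effect), "increases")
  # reliable synapse, weak synchronous facilitation: both rates fall
  hi <- pick(0.95, 0.05)
  expect_equal(as.character(hi$rate_effect), "decreases")
  expect_equal(as.character(hi$energy_effect), "decreases")
})

test_that("weaker asynchronous release widens the beneficial regime", {
  frac_inc <- function(q1v) {
    g <- sweep_grid(axes = list(u = seq(0.05, 0.95, by = 0.09),
                                p1 = seq(0.05, 0.95, by = 0.09)),
                    fixed = list(q1 = q1v, v = 0.5, pmax = 1,
                                 qmax = 4 * q1v, alpha = 0.3))
    m <- effect_map(g)
    c(rate = mean(m$rate_effect == "increases"),
      energy = mean(m$energy_effect == "increases"))
  }
  hi <- frac_inc(0.1); lo <- frac_inc(0.01)
  expect_gt(lo[["rate"]], hi[["rate"]])
  expect_gt(lo[["energy"]], hi[["energy"]])
})

test_that("correlated-input classification agrees with the analytic map", {
  # a point the analytic bounds classify unambiguously at alpha = 0.3
  eff <- classify_effect(synapse_params(0.1, 0.05, 1, 0.2, 0.8, 0.5), 0.3)
  expect_equal(as.character(eff$rate_effect), "increases")
  tab <- correlated_input_experiment(
    p1_values = 0.1, u_values = 0.8, amplitudes = 0,
    n_bins = 4e4, n_trials = 6, seed = 601)
  expect_equal(as.character(tab$rate_effect), "increases")
  expect_true(tab$rate_diff > 0)
})

test_that("experiments are reproducible byte for byte under a fixed seed", {
  run <- function() {
    tab <- correlated_input_experiment(
      p1_values = 0.3, u_values = 0.5, amplitudes = c(0, 0.15),
      n_bins = 5e3, n_trials = 3, seed = 602)
    f <- tempfile(fileext = ".csv")
    write.csv(tab, f, row.names = FALSE)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run(), run())
  t1 <- compare_models(0.5, 0.3, n = 2e4, seed = 603)
  t2 <- compare_models(0.5, 0.3, n = 2e4, seed = 603)
  expect_identical(t1, t2)
})

test_that("model comparison reduces to the memoryless channel when static", {
  tab <- compare_models(p1_values = 0.5, alpha_values = 0.3, u = 0, v = 0,
                        n = 1e6, seed = 604)
  truth <- single_state_rate(0.5, 0.05, 0.3)
  expect_lt(abs(tab$mi_two_state - truth), 0.01)
  expect_lt(abs(tab$mi_general - truth), 0.01)
})

test_that("PSTH reconstruction recovers the programmed sinusoid amplitude", {
  sig <- rate_signal(baseline = 0.3, amplitude = 0.15, frequency = 1,
                     bin_width = 1, n_bins = 2000)
  prof <- estimate_rate_profile(sig, n_trials = 1000, seed = 605)
  t_s <- prof$t / 1000
  fit <- lm(alpha_hat ~ sin(2 * pi * t_s) + cos(2 * pi * t_s), data = prof)
  amp_hat <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp_hat - 0.15) / 0.15, 0.1)
})
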