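test_that("a single trajectory gives indicator-function occupancies", {
  # convention: a state is occupied strictly before its hop time, so the
  # step functions are right-continuous (down-step at the hop instant)
  ht <- hop_frame(10, 500, 1000)
  grid <- c(0, 5, 10, 11, 499, 500, 501, 1000)
  pops <- normalized_occupancies(ht, grid)
  expect_equal(pops$s2, c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(pops$s1, c(0, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(pops$s0, c(0, 0, 0, 0, 0, 1, 1, 1))
})

test_that("occupancies are a partition of unity with the stated initial conditions", {
  for (seed in 1:5) {
    ht <- sample_hop_times(12, 0.5, 150, 3000, seed = seed)
    pops <- normalized_occupancies(ht)
    expect_lt(max(abs(pops$s2 + pops$s1 + pops$s0 - 1)), 1e-12)
    expect_true(all(pops$s2 >= 0 & pops$s2 <= 1))
    expect_true(all(pops$s1 >= 0 & pops$s1 <= 1))
    expect_true(all(pops$s0 >= 0 & pops$s0 <= 1))
    expect_equal(pops$s2[1], 1)
    expect_equal(pops$s1[1], 0)
  }
  expect_error(normalized_occupancies(hop_frame(numeric(0), numeric(0),
                                                100)), "empty")
})

test_that("the closed-form kinetics solve the rate equations (ODE oracle, 1e-9)", {
  tau2 <- 9.5; tau1 <- 830
  grid <- seq(0, 4000, by = 5)
  k <- kinetic_model_solution(tau2, tau1, grid)
  f <- function(t, y, p) list(c(-y[1] / tau2, y[1] / tau2 - y[2] / tau1))
  out <- deSolve::ode(c(1, 0), grid, f, NULL, rtol = 1e-12, atol = 1e-13)
  expect_lt(max(abs(k$s2 - out[, 2])), 1e-9)
  expect_lt(max(abs(k$s1 - out[, 3])), 1e-9)
  expect_lt(max(abs(k$s0 - (1 - out[, 2] - out[, 3]))), 1e-9)

  expect_equal(unlist(kinetic_model_solution(10, 1000, 0)), c(s2 = 1, s1 = 0, s0 = 0))
  expect_error(kinetic_model_solution(-1, 10, 0), "positive")
})

test_that("the equal-lifetime limit is continuous and the tau2 -> 0 limit is single-exponential", {
  t <- seq(0, 500, 10)
  near <- kinetic_model_solution(100 * (1 + 1e-9), 100, t)
  at <- kinetic_model_solution(100, 100, t)
  expect_equal(near$s1, at$s1, tolerance = 1e-6)
  expect_equal(at$s1, (t / 100) * exp(-t / 100), tolerance = 1e-12)

  lim <- kinetic_model_solution(1e-9, 200, t[-1])
  expect_equal(lim$s1, exp(-t[-1] / 200), tolerance = 1e-6)
})

test_that("fitting noiseless model curves recovers the lifetimes to optimizer precision", {
  grid <- seq(0, 50000, length.out = 4001)
  k <- kinetic_model_solution(10, 10000, grid)
  pops <- structure(list(times = grid, s2 = k$s2, s1 = k$s1, s0 = k$s0,
                         n_traj = 1000), class = "swarm_populations")
  ft <- fit_lifetimes(pops)
  expect_equal(ft$tau2_fs, 10, tolerance = 1e-6)
  expect_equal(ft$tau1_ps, 10, tolerance = 1e-6)

  # grid refinement leaves the noiseless fit unchanged
  grid2 <- seq(0, 50000, length.out = 16001)
  k2 <- kinetic_model_solution(10, 10000, grid2)
  pops2 <- structure(list(times = grid2, s2 = k2$s2, s1 = k2$s1,
                          s0 = k2$s0, n_traj = 1000),
                     class = "swarm_populations")
  ft2 <- fit_lifetimes(pops2)
  expect_equal(ft2$tau2_fs, ft$tau2_fs, tolerance = 1e-6)
  expect_equal(ft2$tau1_ps, ft$tau1_ps, tolerance = 1e-6)
})

test_that("an ensemble of identical trajectories has zero extrapolated spread", {
  n <- 120
  ht <- hop_frame(rep(8, n), rep(400, n), 2000)
  err <- subset_error_extrapolation(ht, seed = 1)
  expect_equal(err$sigma_tau2_fs, 0)
  expect_equal(err$sigma_tau1_ps, 0)
})

test_that("extrapolated spread shrinks when the swarm doubles", {
  ht1 <- sample_hop_times(10, 1, 100, 15000, seed = 21)
  ht2 <- sample_hop_times(10, 1, 200, 15000, seed = 21)
  grid <- seq(0, 15000, length.out = 3001)
  fit_fn <- function(sub) {
    ft <- fit_lifetimes(normalized_occupancies(sub, grid))
    c(ft$tau2_fs, ft$tau1_ps * 1000)
  }
  e1 <- subset_error_extrapolation(ht1, fit_fn, seed = 5)
  e2 <- subset_error_extrapolation(ht2, fit_fn, seed = 5)
  expect_lt(e2$sigma_tau1_ps, e1$sigma_tau1_ps)

  expect_error(subset_error_extrapolation(ht1[1:60, ], fit_fn, seed = 1),
               "division levels")
})

test_that("two-state swarms fall back to a single-exponential S1 fit", {
  set.seed(33)
  t10 <- rexp(300, 1 / 250)
  ht <- hop_frame(rep(0, 300), t10, 5000)
  ht$t_hop_21 <- 1e-12   # effectively instantaneous S2 departure
  pops <- normalized_occupancies(ht, seq(0, 5000, length.out = 2001))
  pops$s2[] <- 0         # exact two-state limit
  ft <- fit_lifetimes(pops)
  expect_true(is.na(ft$tau2_fs))
  expect_equal(ft$tau1_ps * 1000, 250, tolerance = 0.15)
})
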