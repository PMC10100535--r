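test_that("a free particle moves uniformly and Verlet is time reversible", {
  st <- phase_space_state(c(0, 1), c(0.1, -0.2), c(2, 3))
  free <- function(x) numeric(2)
  s <- st
  for (i in 1:50) s <- velocity_verlet_step(s, free, 0.5)
  expect_equal(s$positions, st$positions + st$velocities * 25,
               tolerance = 1e-14)
  expect_equal(s$velocities, st$velocities)

  # reversing the time step retraces a harmonic trajectory
  hf <- function(x) -2 * x
  s <- phase_space_state(0.7, 0, 5)
  for (i in 1:200) s <- velocity_verlet_step(s, hf, 0.2)
  for (i in 1:200) s <- velocity_verlet_step(s, hf, -0.2)
  expect_equal(s$positions, 0.7, tolerance = 1e-10)
  expect_equal(s$velocities, 0, tolerance = 1e-10)
})

test_that("harmonic-oscillator energy is stable over 1e4 Verlet steps at T/100", {
  k_ev <- 3; m <- 10
  mech <- surfhop_constants()$ev_mech
  omega <- sqrt(k_ev * mech / m)
  period <- 2 * pi / omega
  dt <- period / 100
  force <- function(x) list(force = -k_ev * x, energy = 0.5 * k_ev * x^2)
  s <- phase_space_state(0.5, 0, m)
  e0 <- 0.5 * k_ev * 0.25
  drift <- 0
  for (i in 1:10000) {
    s <- velocity_verlet_step(s, force, dt)
    e <- s$potential_energy + 0.5 * m * s$velocities^2 / mech
    drift <- max(drift, abs(e - e0) / e0)
  }
  # velocity Verlet has a bounded oscillatory energy error of leading
  # order (omega dt)^2; require no secular growth beyond that scale
  expect_lt(drift, (omega * dt)^2)
})

test_that("non-finite forces abort with a geometry dump", {
  bad <- function(x) rep(NaN, length(x))
  s <- phase_space_state(1.25, 0, 1)
  expect_error(velocity_verlet_step(s, bad, 0.1), "1.25")
})

test_that("the Andersen thermostat resamples only masked DOFs and honours nu = 0", {
  p <- partition_system(10, 1:3)
  set.seed(5)
  s <- phase_space_state(rnorm(10), rnorm(10, 0, 0.01), rep(15, 10),
                         partition = p)
  s0 <- s
  expect_identical(andersen_thermostat(s, 4:10, 298, 0, 0.5), s)

  set.seed(6)
  s1 <- andersen_thermostat(s, 4:10, 298, 5, 0.5)
  expect_identical(s1$velocities[1:3], s0$velocities[1:3])
  expect_false(all(s1$velocities[4:10] == s0$velocities[4:10]))

  expect_error(andersen_thermostat(s, 3:10, 298, 1, 0.5),
               "touches QM region at index 3")
})

test_that("thermostatted harmonic solvent converges to Maxwell-Boltzmann equipartition", {
  # 100 solvent DOFs behind a 1-DOF solute, 1500 steps: 1.5e5 samples
  n <- 101
  p <- partition_system(n, 1)
  masses <- c(12, rep(18, n - 1))
  k_ev <- 1.5
  force <- function(x) -k_ev * x
  set.seed(7)
  s <- phase_space_state(rnorm(n, 0, 0.05), numeric(n), masses,
                         partition = p)
  kT <- surfhop_constants()$kb_ev * 298
  mech <- surfhop_constants()$ev_mech
  ke <- 0
  n_samp <- 0
  for (i in 1:2500) {
    s <- velocity_verlet_step(s, force, 0.5)
    s <- andersen_thermostat(s, 2:n, 298, 0.3, 0.5)
    if (i > 200) {
      ke <- ke + sum(0.5 * masses[-1] * s$velocities[-1]^2 / mech)
      n_samp <- n_samp + n - 1
    }
  }
  expect_gt(n_samp, 1e5)
  expect_equal(ke / n_samp, kT / 2, tolerance = 0.03)
})

test_that("ground-state run returns the arithmetic snapshot count and is seed deterministic", {
  m <- make_avoided_crossing_model(3)
  cfg <- sampling_config(t_ground_ps = 0.05, stride = 10, seed = 3,
                         collision_frequency = 0)
  st <- phase_space_state(0, 0, m$masses)
  snaps <- run_ground_state_md(st, list(model = m), cfg)
  expect_length(snaps, 10)   # 50 fs / (0.5 fs x 10)
  expect_named(snaps[[1]], c("state", "time", "energies", "f", "e_total"))

  snaps2 <- run_ground_state_md(st, list(model = m), cfg)
  expect_identical(snaps, snaps2)
})

test_that("initial-condition selection applies both criteria as a pure filter", {
  fake <- function(de, f2) list(
    state = phase_space_state(0, 0, 12), time = 0,
    energies = c(0, de / 2, de), f = c(0, 0.01, f2), e_total = 0)
  snaps <- Map(fake, c(3.9, 4.1, 4.3, 4.5, 4.7), c(.2, .0, .3, .4, .0))

  sel <- select_initial_conditions(snaps, c(4.0, 4.6), 0.1)
  expect_length(sel, 2)
  expect_equal(vapply(sel, function(ic) ic$excitation_energy, 0),
               c(4.3, 4.5))
  expect_equal(sel[[1]]$start_surface, 2L)

  all_sel <- select_initial_conditions(snaps, c(-Inf, Inf), 0)
  expect_length(all_sel, 5)

  expect_warning(sel0 <- select_initial_conditions(snaps, c(4.0, 4.6), 1.0),
                 "empty")
  expect_length(sel0, 0)

  # idempotence through re-filtering the surviving snapshots
  surviving <- snaps[c(3, 4)]
  again <- select_initial_conditions(surviving, c(4.0, 4.6), 0.1)
  expect_length(again, 2)
})
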