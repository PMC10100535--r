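test_that("uncoupled constant states evolve by pure phases with frozen populations", {
  hbar <- surfhop_constants()$hbar_evfs
  E <- c(0.3, 1.7)
  snap <- const_snapshot(E, 0)
  c0 <- c(sqrt(0.3), sqrt(0.7) * 1i)
  a <- electronic_amplitudes(c0, 0)
  t_tot <- 0
  for (i in 1:50) {
    a <- propagate_amplitudes(a, snap, snap, 0.1, 10)
    t_tot <- t_tot + 0.1
  }
  expect_equal(a$c, c0 * exp(-1i * E * t_tot / hbar), tolerance = 1e-12)
  expect_equal(Mod(a$c)^2, Mod(c0)^2, tolerance = 1e-12)
})

test_that("amplitude norm is conserved to 1e-8 per step for random couplings", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(2:3, 1)
    E <- sort(runif(n, 0, 4))
    sg <- matrix(0, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      sg[a, b] <- rnorm(1, 0, 0.3)
      sg[b, a] <- -sg[a, b]
    }
    s0 <- structure(list(energies = E, sigma = sg,
                         nac = array(0, c(n, n, 1))),
                    class = "coupling_snapshot")
    s1 <- structure(list(energies = E + rnorm(n, 0, 0.05),
                         sigma = sg * runif(1, 0.5, 1.5),
                         nac = array(0, c(n, n, 1))),
                    class = "coupling_snapshot")
    cc <- complex(real = rnorm(n), imaginary = rnorm(n))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    amps <- electronic_amplitudes(cc, 0)
    amps <- propagate_amplitudes(amps, s0, s1, 0.1, 20)
    expect_lt(abs(sum(Mod(amps$c)^2) - 1), 1e-8)
  }
})

test_that("propagation matches the exact propagator of a constant Hamiltonian", {
  # 2-state and 3-state, against an independent high-accuracy ODE oracle
  for (n in 2:3) {
    set.seed(n)
    E <- sort(runif(n, 0, 3))
    sg <- matrix(0, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      sg[a, b] <- runif(1, -0.2, 0.2)
      sg[b, a] <- -sg[a, b]
    }
    snap <- structure(list(energies = E, sigma = sg,
                           nac = array(0, c(n, n, 1))),
                      class = "coupling_snapshot")
    cc <- complex(real = rnorm(n), imaginary = rnorm(n))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    amps <- electronic_amplitudes(cc, 0)
    out <- propagate_amplitudes(amps, snap, snap, 0.1, 20)
    ref <- ode_amplitude_oracle(cc, E, sg, 0.1)
    expect_lt(max(Mod(out$c - ref)), 1e-6)
  }
})

test_that("hop probabilities implement the rectified fewest-switches formula", {
  snap <- const_snapshot(c(0, 1), 0.01)
  # zero coupling: no hops
  amps <- electronic_amplitudes(c(sqrt(0.5), sqrt(0.5)), 0)
  expect_equal(hop_probabilities(amps, const_snapshot(c(0, 1), 0), 0.1),
               c(0, 0))

  # hand-evaluated case: c = (0.8, 0.6 i exp(i phi)), sigma_12 = 0.01/fs
  phi <- -0.4
  cc <- c(0.8, 0.6i * exp(1i * phi))
  amps <- electronic_amplitudes(cc, 0)
  g <- hop_probabilities(amps, snap, 0.1)
  # 2 dt Re(c2 c1* sigma_12)/|c1|^2 = 2*0.1*0.8*0.6*(-sin(phi))*0.01/0.64
  manual <- 2 * 0.1 * 0.8 * 0.6 * (-sin(phi)) * 0.01 / 0.64
  expect_equal(g[2], manual, tolerance = 1e-12)

  # the sign-reversed phase makes the raw expression negative: clamped
  ampsr <- electronic_amplitudes(c(0.8, 0.6i * exp(-1i * phi)), 0)
  expect_equal(hop_probabilities(ampsr, snap, 0.1)[2], 0)

  # occupied-amplitude collapse yields zero probabilities with a warning
  tiny <- structure(list(c = c(1e-8 + 0i, sqrt(1 - 1e-16) + 0i),
                         current_surface = 0L, n_renorm = 0L),
                    class = "el_amplitudes")
  expect_warning(g0 <- hop_probabilities(tiny, snap, 0.1), "collapsed")
  expect_equal(g0, c(0, 0))
})

test_that("hops conserve total energy exactly and frustrated hops leave velocities untouched", {
  # d_21 = (0.4, -0.2, 0.1) with its antisymmetric partner
  d <- c(0.4, -0.2, 0.1)
  nac <- array(0, c(2, 2, 3))
  nac[2, 1, ] <- d
  nac[1, 2, ] <- -d
  snap <- structure(list(energies = c(0, 0.8),
                         sigma = matrix(c(0, -0.1, 0.1, 0), 2, 2),
                         nac = nac), class = "coupling_snapshot")
  mech <- surfhop_constants()$ev_mech

  # downhill hop (from S1 to S0) always allowed, energy conserved
  st <- phase_space_state(c(0, 0, 0), c(0.02, 0.01, -0.005), c(12, 1, 16))
  amps <- electronic_amplitudes(c(sqrt(0.5), sqrt(0.5)), 1)
  e_before <- snap$energies[2] + 0.5 * sum(st$masses * st$velocities^2) / mech
  set.seed(1)
  hop <- attempt_hop(c(1, 0), st, snap, amps)
  expect_equal(hop$new_surface, 0L)
  e_after <- snap$energies[1] +
    0.5 * sum(hop$state$masses * hop$state$velocities^2) / mech
  expect_lt(abs(e_after - e_before), 1e-8)

  # uphill with insufficient kinetic energy along d: frustrated
  slow <- phase_space_state(c(0, 0, 0), c(1e-4, 0, 0), c(12, 1, 16))
  amps0 <- electronic_amplitudes(c(sqrt(0.5), sqrt(0.5)), 0)
  set.seed(2)
  fh <- attempt_hop(c(0, 1), slow, snap, amps0)
  expect_equal(fh$new_surface, 0L)
  expect_identical(fh$state$velocities, slow$velocities)
  expect_true(fh$event$frustrated)

  # zero probability vector: never hops for any draw
  set.seed(3)
  for (i in 1:20) {
    nh <- attempt_hop(c(0, 0), st, snap, amps)
    expect_equal(nh$new_surface, 1L)
    expect_null(nh$event)
  }
})

test_that("a trajectory with no reachable coupling stays on its surface", {
  m <- make_avoided_crossing_model(2, linear_crossing_params(rc = 100))
  cfg <- sampling_config(collision_frequency = 0)
  st <- phase_space_state(0, 0.01, 10)
  tr <- run_hopping_trajectory(st, list(model = m), cfg, t_max_fs = 20,
                               seed = 1)
  expect_true(all(tr$surface_history == 1L))
  expect_equal(nrow(tr$hop_events), 0)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- make_avoided_crossing_model(3)
  cfg <- sampling_config(collision_frequency = 0)
  st <- phase_space_state(0, 0.02, m$masses)
  tr1 <- run_hopping_trajectory(st, list(model = m), cfg, t_max_fs = 40,
                                seed = 9)
  tr2 <- run_hopping_trajectory(st, list(model = m), cfg, t_max_fs = 40,
                                seed = 9)
  expect_identical(tr1$surface_history, tr2$surface_history)
  expect_identical(tr1$energy_history, tr2$energy_history)
})

test_that("ensemble S0 occupancy grows with the simulation horizon", {
  m <- make_avoided_crossing_model(2)
  cfg <- sampling_config(collision_frequency = 0)
  kT <- surfhop_constants()$kb_ev * 298
  mech <- surfhop_constants()$ev_mech
  trajs <- list()
  set.seed(10)
  for (i in 1:40) {
    v0 <- rnorm(1, 0, sqrt(kT * mech / m$masses))
    x0 <- rnorm(1, 0, 0.1)
    st <- phase_space_state(x0, v0, m$masses)
    trajs[[i]] <- run_hopping_trajectory(st, list(model = m), cfg,
                                         t_max_fs = 120, seed = 2000 + i)
  }
  pops <- normalized_occupancies(trajs, grid = c(20, 60, 120))
  expect_true(all(diff(pops$s0) >= 0))
  expect_gt(pops$s0[3], 0)
})

test_that("single-passage hop statistics agree with the Landau-Zener estimate", {
  # high-velocity passage through one localized crossing; wide tolerance:
  # FSSH reproduces the diabatic-passage probability only statistically
  hbar <- surfhop_constants()$hbar_evfs
  mech <- surfhop_constants()$ev_mech
  A <- 0.085
  p <- list(n_dof = 1, masses = 20,
            states = list(list(e0 = 0, a = 1, k = 0, r0 = 0),
                          list(e0 = 0, a = -1, k = 0, r0 = 0)),
            couplings = list(list(states = c(0, 1), amp = A, rc = 0,
                                  w = 0.2)),
            f_diab = c(0, 1))
  m <- make_avoided_crossing_model(2, p)
  cfg <- sampling_config(collision_frequency = 0)
  v0 <- 0.06
  n <- 80
  hops <- 0
  for (i in 1:n) {
    st <- phase_space_state(-1, v0, 20)
    tr <- run_hopping_trajectory(st, list(model = m), cfg, t_max_fs = 25,
                                 seed = 3000 + i)
    if (tr$surface_history[length(tr$surface_history)] == 0L)
      hops <- hops + 1
  }
  # velocity at the crossing from energy conservation on the upper adiabat
  e_start <- evaluate_surface(m, -1)$energies[2] + 0.5 * 20 * v0^2 / mech
  ke_x <- (e_start - evaluate_surface(m, 0)$energies[2]) * mech
  v_x <- sqrt(2 * ke_x / 20)
  p_lz <- exp(-2 * pi * A^2 / (hbar * v_x * 2))   # |dF| = 2 eV/A
  expect_lt(abs(hops / n - p_lz), 0.15)
})

test_that("the ensemble surface/electronic-population consistency record is produced", {
  m <- make_avoided_crossing_model(3)
  cfg <- sampling_config(collision_frequency = 0)
  st <- phase_space_state(0, 0.02, m$masses)
  trajs <- lapply(1:3, function(i)
    run_hopping_trajectory(st, list(model = m), cfg, t_max_fs = 30,
                           seed = 100 + i, record_amplitudes = 10))
  cons <- swarm_consistency(trajs)
  expect_true(all(is.finite(as.matrix(cons))))
  expect_equal(cons$surface_S0 + cons$surface_S1 + cons$surface_S2,
               rep(1, nrow(cons)))
})
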