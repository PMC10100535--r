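#' Phase-space state of the combined solute + environment system
#'
#' A flat-coordinate container for classical nuclear dynamics: positions
#' (A), velocities (A/fs), per-DOF masses (amu), time (fs), and the QM/MM
#' region partition.  An optional cached `force` (eV/A) avoids re-evaluating
#' the engine at an unchanged geometry inside the integrator.
#'
#' @param positions,velocities,masses Numeric vectors of equal length.
#' @param time Current time in fs.
#' @param partition Optional `region_partition` over the coordinates.
#' @return An object of class `phase_space_state`.
#' @export
phase_space_state <- function(positions, velocities, masses, time = 0,
                              partition = NULL) {
  positions <- as.numeric(positions)
  velocities <- as.numeric(velocities)
  masses <- as.numeric(masses)
  if (length(velocities) != length(positions) ||
      length(masses) != length(positions))
    stop("positions, velocities and masses must have equal length")
  if (!all(is.finite(positions)) || !all(is.finite(velocities)))
    stop("non-finite phase-space entries")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(positions = positions, velocities = velocities,
                 masses = masses, time = time, partition = partition,
                 force = NULL),
            class = "phase_space_state")
}

#' One velocity-Verlet step
#'
#' Standard symplectic position/velocity update under forces from
#' `force_fn`, advancing time by `dt`.  `force_fn(positions)` may return a
#' bare numeric force vector (eV/A) or `list(force, energy)`; a returned
#' energy is cached on the state as `potential_energy`.
#'
#' @param state A `phase_space_state`.
#' @param force_fn Force callback (eV/A as a function of positions).
#' @param dt Time step in fs (> 0).
#' @return The advanced `phase_space_state` (force cached for the next
#'   step).
#' @export
velocity_verlet_step <- function(state, force_fn, dt) {
  stopifnot(inherits(state, "phase_space_state"), dt != 0)
  if (is.null(state$force)) {
    f <- .as_force(force_fn(state$positions), state)
    state$force <- f$force
    state$potential_energy <- f$energy
  }
  a <- state$force * .EV_MECH / state$masses
  x_new <- state$positions + state$velocities * dt + 0.5 * a * dt^2
  f_new <- .as_force(force_fn(x_new), state, x_new)
  a_new <- f_new$force * .EV_MECH / state$masses
  state$positions <- x_new
  state$velocities <- state$velocities + 0.5 * (a + a_new) * dt
  state$force <- f_new$force
  state$potential_energy <- f_new$energy
  state$time <- state$time + dt
  state
}

.as_force <- function(res, state, at = NULL) {
  out <- if (is.list(res)) list(force = as.numeric(res$force),
                                energy = res$energy)
         else list(force = as.numeric(res), energy = NULL)
  if (!all(is.finite(out$force)))
    stop("non-finite force at t = ", format(state$time), " fs; geometry: ",
         paste(format(if (is.null(at)) state$positions else at,
                      digits = 6), collapse = " "))
  out
}

#' Andersen thermostat on the solvent only
#'
#' Each masked degree of freedom is independently redrawn from the
#' Maxwell-Boltzmann distribution at the target temperature with collision
#' probability `1 - exp(-nu * dt)` per call; unmasked (solute) velocities
#' are left bit-identical.  When the state carries a region partition the
#' mask must lie entirely inside the MM region.
#'
#' @param state A `phase_space_state`.
#' @param solvent_mask Logical vector over DOFs, or integer DOF indices.
#' @param temperature Target temperature in K.
#' @param collision_frequency Collision rate `nu` in 1/fs (>= 0).
#' @param dt Time step between thermostat calls, fs.
#' @return The state with resampled solvent velocities.
#' @export
andersen_thermostat <- function(state, solvent_mask, temperature,
                                collision_frequency, dt) {
  stopifnot(inherits(state, "phase_space_state"),
            collision_frequency >= 0, temperature > 0, dt > 0)
  idx <- if (is.logical(solvent_mask)) which(solvent_mask)
         else as.integer(solvent_mask)
  if (!is.null(state$partition)) {
    touch <- intersect(idx, state$partition$qm_indices)
    if (length(touch) > 0)
      stop("thermostat mask touches QM region at index ", touch[1])
  }
  if (collision_frequency == 0 || length(idx) == 0) return(state)
  p <- 1 - exp(-collision_frequency * dt)
  hit <- idx[stats::runif(length(idx)) < p]
  if (length(hit) > 0)
    state$velocities[hit] <- .mb_velocities(state$masses[hit], temperature)
  state
}

#' Sampling configuration for ground-state and hopping dynamics
#'
#' @param dt_ground Ground-state MD time step, fs (default 0.5).
#' @param dt_hopping Hopping-dynamics time step, fs (default 0.1).
#' @param t_ground_ps Ground-state trajectory length, ps (default 10).
#' @param temperature Bath temperature, K (default 298).
#' @param collision_frequency Andersen collision rate, 1/fs (default 0.01).
#' @param stride Snapshot stride in ground-state steps (default 10),
#'   spacing out initial conditions so they decorrelate.
#' @param seed Integer seed for all stochastic elements of the run.
#' @param energy_bound Abort threshold: ground-state run truncates when the
#'   total energy rises more than this many eV above its initial value.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(dt_ground = 0.5, dt_hopping = 0.1,
                            t_ground_ps = 10, temperature = 298,
                            collision_frequency = 0.01, stride = 10,
                            seed = 1, energy_bound = 50) {
  stopifnot(dt_ground > 0, dt_hopping > 0,
            t_ground_ps * 1000 >= dt_ground, temperature > 0,
            collision_frequency >= 0, stride >= 1)
  structure(list(dt_ground = dt_ground, dt_hopping = dt_hopping,
                 t_ground_ps = t_ground_ps, temperature = temperature,
                 collision_frequency = collision_frequency,
                 stride = as.integer(stride), seed = as.integer(seed),
                 energy_bound = energy_bound),
            class = "sampling_config")
}

#' Ground-state molecular dynamics with snapshot collection
#'
#' Propagates the full system on the ground-state surface (forces from the
#' subtractive QM/MM combination), thermostatting the solvent, and stores a
#' snapshot every `config$stride` steps.  Each snapshot carries the
#' phase-space state plus the vertical excitation data (adiabatic energies
#' and surrogate oscillator strengths at the QM geometry) that the
#' initial-condition selection consumes.
#'
#' @param initial A `phase_space_state` with a partition.
#' @param engines List with `model` (the `model_surface` for the QM region)
#'   and optionally `low_engine` (low-level engine over the full system;
#'   defaults to [zero_engine()], the gas-phase limit).
#' @param config A `sampling_config`.
#' @return List of snapshots; each is `list(state, time, energies, f,
#'   e_total)`.  Truncates with a warning if the total energy exceeds
#'   `config$energy_bound` above its starting value.
#' @export
run_ground_state_md <- function(initial, engines, config) {
  stopifnot(inherits(initial, "phase_space_state"),
            inherits(config, "sampling_config"))
  model <- engines$model
  stopifnot(inherits(model, "model_surface"))
  partition <- initial$partition
  if (is.null(partition))
    partition <- partition_system(length(initial$positions),
                                  seq_len(model$n_dof))
  initial$partition <- partition
  low <- if (is.null(engines$low_engine)) zero_engine()
         else engines$low_engine
  high <- qm_state_engine(model, 0L)

  force_fn <- function(x) {
    se <- subtractive_energy_and_gradient(partition, high, low, x)
    list(force = -se$gradient_total, energy = se$e_total)
  }

  set.seed(config$seed)
  n_steps <- round(config$t_ground_ps * 1000 / config$dt_ground)
  state <- initial
  state$force <- NULL
  snapshots <- vector("list", n_steps %/% config$stride + 1L)
  n_snap <- 0L
  e0 <- NULL
  for (step in seq_len(n_steps)) {
    state <- velocity_verlet_step(state, force_fn, config$dt_ground)
    if (length(partition$mm_indices) > 0)
      state <- andersen_thermostat(state, partition$mm_indices,
                                   config$temperature,
                                   config$collision_frequency,
                                   config$dt_ground)
    e_tot <- state$potential_energy +
      .kinetic_energy_ev(state$velocities, state$masses)
    if (is.null(e0)) e0 <- e_tot
    if (e_tot - e0 > config$energy_bound) {
      warning("energy blow-up at t = ", format(state$time),
              " fs (", format(e_tot - e0, digits = 4),
              " eV above start); run truncated")
      break
    }
    if (step %% config$stride == 0L) {
      es <- evaluate_surface(model, state$positions[partition$qm_indices])
      n_snap <- n_snap + 1L
      snapshots[[n_snap]] <- list(state = state, time = state$time,
                                  energies = es$energies, f = es$f,
                                  e_total = e_tot)
    }
  }
  snapshots[seq_len(n_snap)]
}

#' Select initial conditions for the hopping swarm
#'
#' Filters ground-state snapshots by the two selection criteria used to
#' launch excited-state trajectories: (a) the vertical excitation energy to
#' the target state must fall inside `energy_window`, and (b) the transition
#' strength to that state must exceed `strength_threshold`.  Retained
#' snapshots are tagged with the starting surface.  The filter is pure:
#' output is a subset of input, order-preserving and idempotent.
#'
#' @param snapshots Snapshot list from [run_ground_state_md()].
#' @param energy_window Numeric length-2 `c(lo, hi)` in eV.
#' @param strength_threshold Minimum oscillator strength (dimensionless).
#' @param start_surface 0-based target electronic state; defaults to the
#'   second excited state (or the highest state of a 2-state model).
#' @return List of `initial_condition` objects: `state`, `start_surface`,
#'   `excitation_energy` (eV), `transition_strength`.  Warns (does not fail
#'   silently) when the selection is empty.
#' @export
select_initial_conditions <- function(snapshots, energy_window,
                                      strength_threshold,
                                      start_surface = NULL) {
  stopifnot(length(energy_window) == 2, energy_window[1] <= energy_window[2])
  if (length(snapshots) == 0) stop("no snapshots supplied")
  n_states <- length(snapshots[[1]]$energies)
  if (is.null(start_surface)) start_surface <- min(2L, n_states - 1L)
  i <- as.integer(start_surface) + 1L
  stopifnot(i >= 2, i <= n_states)

  out <- list()
  for (snap in snapshots) {
    de <- snap$energies[i] - snap$energies[1]
    f <- snap$f[i]
    if (de >= energy_window[1] && de <= energy_window[2] &&
        f >= strength_threshold) {
      out[[length(out) + 1L]] <- structure(
        list(state = snap$state, start_surface = as.integer(start_surface),
             excitation_energy = de, transition_strength = f),
        class = "initial_condition")
    }
  }
  if (length(out) == 0)
    warning("initial-condition selection is empty: no snapshot satisfies ",
            "the energy window [", energy_window[1], ", ", energy_window[2],
            "] eV with strength >= ", strength_threshold)
  out
}
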