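#' Electronic amplitudes on the adiabatic basis
#'
#' Complex coefficients `c_a(t)` of the time-dependent electronic
#' wavefunction expanded in the adiabatic states, plus the index of the
#' currently occupied surface.  The norm `sum |c_a|^2` must be 1.
#'
#' @param c Complex (or numeric) coefficient vector, one per state.
#' @param current_surface 0-based index of the occupied adiabatic state.
#' @return Object of class `el_amplitudes`.
#' @export
electronic_amplitudes <- function(c, current_surface) {
  c <- as.complex(c)
  nrm <- sum(Mod(c)^2)
  if (abs(nrm - 1) > 1e-8)
    stop("amplitude norm is ", format(nrm), "; must be 1")
  stopifnot(current_surface >= 0, current_surface < length(c))
  structure(list(c = c, current_surface = as.integer(current_surface),
                 n_renorm = 0L),
            class = "el_amplitudes")
}

#' Coupling snapshot at one trajectory point
#'
#' Packages what the electronic propagation needs at a step endpoint:
#' adiabatic energies and the scalar time-derivative couplings
#' `sigma_kj = R' . d_kj` (antisymmetric, zero diagonal) obtained by
#' contracting the nonadiabatic coupling vectors with the QM-region nuclear
#' velocities.
#'
#' @param es An `el_structure` from [evaluate_surface()].
#' @param v_qm QM-region velocity vector (A/fs).
#' @return Object of class `coupling_snapshot` with `energies` (eV),
#'   `sigma` (n x n, 1/fs), and the `nac` array carried through for
#'   velocity rescaling.
#' @export
coupling_snapshot <- function(es, v_qm) {
  n <- length(es$energies)
  sigma <- matrix(0, n, n)
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (k == j) next
    sigma[k, j] <- sum(v_qm * es$nac[k, j, ])
  }
  structure(list(energies = es$energies, sigma = sigma, nac = es$nac),
            class = "coupling_snapshot")
}

#' Propagate electronic amplitudes across one nuclear step
#'
#' Integrates the amplitude equations
#' `i hbar dc_k/dt = sum_j c_j (H_kj - i hbar sigma_kj)` with `H` diagonal
#' in the adiabatic basis, interpolating energies and time-derivative
#' couplings linearly between the step endpoints.  Each electronic substep
#' applies the exact unitary propagator of the (Hermitian) effective
#' Hamiltonian at the substep midpoint, so the norm is conserved to machine
#' precision; if the drift in one nuclear step nevertheless exceeds 1e-10
#' the substep count is doubled once, above 1e-8 the amplitudes are
#' renormalized and the event counted in `n_renorm`, and above 1e-4 the
#' trajectory is aborted as numerically unsound.
#'
#' @param amps An `el_amplitudes`.
#' @param snapshot_t,snapshot_t_plus_dt `coupling_snapshot`s at the step
#'   endpoints.
#' @param dt Nuclear time step, fs.
#' @param n_substeps Electronic substeps per nuclear step (>= 1,
#'   default 20).
#' @return The advanced `el_amplitudes`.
#' @export
propagate_amplitudes <- function(amps, snapshot_t, snapshot_t_plus_dt, dt,
                                 n_substeps = 20) {
  stopifnot(inherits(amps, "el_amplitudes"), n_substeps >= 1)
  c_new <- .propagate_c(amps$c, snapshot_t, snapshot_t_plus_dt, dt,
                        n_substeps)
  drift <- abs(sum(Mod(c_new)^2) - 1)
  if (drift > 1e-10 && n_substeps < 4096) {
    c_new <- .propagate_c(amps$c, snapshot_t, snapshot_t_plus_dt, dt,
                          2L * n_substeps)
    drift <- abs(sum(Mod(c_new)^2) - 1)
  }
  if (drift > 1e-4)
    stop("amplitude norm drift ", format(drift),
         " in one step; trajectory numerically unsound")
  if (drift > 1e-8) {
    c_new <- c_new / sqrt(sum(Mod(c_new)^2))
    amps$n_renorm <- amps$n_renorm + 1L
  }
  amps$c <- c_new
  amps
}

.propagate_c <- function(cc, s0, s1, dt, n_sub) {
  h <- dt / n_sub
  n <- length(cc)
  for (m in seq_len(n_sub)) {
    w <- (m - 0.5) / n_sub
    E <- (1 - w) * s0$energies + w * s1$energies
    sg <- (1 - w) * s0$sigma + w * s1$sigma
    if (n == 2L) {
      cc <- .u2_apply(cc, E, sg[1, 2], h)
    } else {
      heff <- diag(E) + (0 - 1i) * .HBAR_EVFS * sg
      eg <- eigen(heff, symmetric = TRUE)
      ph <- exp(-1i * eg$values * h / .HBAR_EVFS)
      cc <- eg$vectors %*% (ph * crossprod(Conj(eg$vectors), cc))
      cc <- as.complex(cc)
    }
  }
  cc
}

# exact 2x2 unitary exp(-i Heff h / hbar) applied to c, via the Pauli
# decomposition of Heff = a0 I + dz sz + dy sy  (dx = 0 for our Heff)
.u2_apply <- function(cc, E, sigma12, h) {
  a0 <- (E[1] + E[2]) / 2
  dz <- (E[1] - E[2]) / 2
  dy <- .HBAR_EVFS * sigma12      # off-diag of Heff is -i hbar sigma12
  dn <- sqrt(dz^2 + dy^2)
  th <- dn * h / .HBAR_EVFS
  phase <- exp(-1i * a0 * h / .HBAR_EVFS)
  if (dn < 1e-300) return(phase * cc)
  cs <- cos(th)
  sn <- sin(th) / dn
  u11 <- phase * (cs - 1i * sn * dz)
  u12 <- phase * (-1i * sn * (0 - 1i * dy))   # -i sn (dx - i dy)
  u21 <- phase * (-1i * sn * (0 + 1i * dy))
  u22 <- phase * (cs + 1i * sn * dz)
  c(u11 * cc[1] + u12 * cc[2], u21 * cc[1] + u22 * cc[2])
}

#' Fewest-switches hop probabilities
#'
#' Tully's fewest-switches prescription for the probability of leaving the
#' occupied state `a` for each state `b` during one step:
#' `g_(a->b) = max(0, 2 dt Re(c_b c_a^* sigma_ab) / |c_a|^2)`,
#' rectified at zero (the fewest-switches choice) and clamped so the total
#' hop probability never exceeds 1.
#'
#' @param amps An `el_amplitudes` (occupied state `a` = `current_surface`).
#' @param snapshot A `coupling_snapshot`.
#' @param dt Time step, fs.
#' @return Numeric probability vector over states (0 at the occupied
#'   state).  If `|c_a|^2 < 1e-12` (occupied-amplitude collapse) all
#'   probabilities are zero and a warning is issued.
#' @export
hop_probabilities <- function(amps, snapshot, dt) {
  stopifnot(inherits(amps, "el_amplitudes"),
            inherits(snapshot, "coupling_snapshot"))
  n <- length(amps$c)
  a <- amps$current_surface + 1L
  pa <- Mod(amps$c[a])^2
  g <- numeric(n)
  if (pa < 1e-12) {
    warning("occupied-state amplitude collapsed (|c|^2 = ",
            format(pa), "); hop probabilities set to zero")
    return(g)
  }
  for (b in seq_len(n)) {
    if (b == a) next
    g[b] <- max(0, 2 * dt *
                  Re(amps$c[b] * Conj(amps$c[a]) * snapshot$sigma[a, b]) /
                  pa)
  }
  s <- sum(g)
  if (s > 1) g <- g / s
  g
}

#' Attempt a stochastic hop with energy-conserving velocity rescaling
#'
#' Draws `u ~ Uniform(0,1)` from the current RNG stream and hops to the
#' state whose cumulative probability bin contains `u`.  On a hop, the
#' QM-region velocity component along the nonadiabatic coupling vector
#' `d_ba` is rescaled so total energy is conserved exactly; if the kinetic
#' energy along that direction cannot pay an uphill gap the hop is
#' frustrated: the surface is kept and (by default) velocities are left
#' unchanged, with the event recorded.  Frustrated hops are events, not
#' errors.
#'
#' @param g Probability vector from [hop_probabilities()].
#' @param state A `phase_space_state` (velocities adjusted on acceptance).
#' @param snapshot A `coupling_snapshot` at the current geometry.
#' @param amps An `el_amplitudes` (for the occupied state index).
#' @param frustrated_reversal If `TRUE`, reverse the velocity component
#'   along the coupling vector on a frustrated hop (off by default).
#' @return `list(new_surface, state, event)`; `event` is `NULL` when no
#'   hop was attempted, otherwise a one-row data frame
#'   `(time, from, to, accepted, frustrated)`.
#' @export
attempt_hop <- function(g, state, snapshot, amps,
                        frustrated_reversal = FALSE) {
  a <- amps$current_surface + 1L
  u <- stats::runif(1)
  cum <- cumsum(g)
  b <- which(u <= cum)[1]
  if (is.na(b) || b == a)
    return(list(new_surface = amps$current_surface, state = state,
                event = NULL))

  qm <- if (!is.null(state$partition)) state$partition$qm_indices
        else seq_along(state$positions)
  d <- snapshot$nac[b, a, ]
  if (any(is.na(d))) d <- numeric(length(qm))
  m <- state$masses[qm]
  v <- state$velocities[qm]
  de_mech <- (snapshot$energies[b] - snapshot$energies[a]) * .EV_MECH

  aa <- sum(d^2 / (2 * m))
  bb <- sum(v * d)
  disc <- bb^2 - 4 * aa * de_mech
  ev <- function(acc, fru) data.frame(time = state$time, from = a - 1L,
                                      to = b - 1L, accepted = acc,
                                      frustrated = fru)
  if (aa == 0) {
    if (abs(de_mech) < 1e-14) {     # degenerate-gap hop, nothing to pay
      return(list(new_surface = b - 1L, state = state,
                  event = ev(TRUE, FALSE)))
    }
    return(list(new_surface = amps$current_surface, state = state,
                event = ev(FALSE, TRUE)))
  }
  if (disc < 0) {                   # frustrated
    if (frustrated_reversal) {
      state$velocities[qm] <- v - 2 * (bb / sum(d^2 / m)) * d / m
    }
    return(list(new_surface = amps$current_surface, state = state,
                event = ev(FALSE, TRUE)))
  }
  roots <- c((bb - sqrt(disc)) / (2 * aa), (bb + sqrt(disc)) / (2 * aa))
  gamma <- roots[which.min(abs(roots))]
  state$velocities[qm] <- v - gamma * d / m
  list(new_surface = b - 1L, state = state, event = ev(TRUE, FALSE))
}

# align NAC signs with the previous step (phase tracking) and patch
# degenerate pairs with the previous step's couplings
.align_nac <- function(es, es_prev) {
  if (is.null(es_prev)) return(es)
  n <- length(es$energies)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    cur <- es$nac[b, a, ]
    prev <- es_prev$nac[b, a, ]
    if (any(is.na(cur))) {
      es$nac[b, a, ] <- prev
      es$nac[a, b, ] <- -prev
    } else if (!any(is.na(prev)) && sum(cur * prev) < 0) {
      es$nac[b, a, ] <- -cur
      es$nac[a, b, ] <- cur
    }
  }
  es
}

#' Run one fewest-switches surface-hopping trajectory
#'
#' Alternates the velocity-Verlet nuclear step (forces from the occupied
#' adiabatic surface, combined with any low-level environment engine by the
#' subtractive scheme), electronic amplitude propagation between the step
#' endpoints, and a fewest-switches hop attempt, until `t_max_fs` or until
#' the trajectory has dwelt on S0 for `s0_dwell_fs`.  Hops between any
#' state pair are allowed, including direct S2 -> S0.  When the surface
#' evaluation flags a degeneracy the previous step's couplings are reused
#' (small-gap protocol); no gap threshold forbids hopping.
#'
#' @param init An `initial_condition` (from [select_initial_conditions()])
#'   or a `phase_space_state`; the starting surface defaults to the second
#'   excited state (highest state of a 2-state model).
#' @param engines List with `model` and optionally `low_engine` as in
#'   [run_ground_state_md()].
#' @param config A `sampling_config`; `dt_hopping` is the step,
#'   `collision_frequency > 0` applies the Andersen thermostat to the MM
#'   region each step (set 0 for NVE).
#' @param t_max_fs Maximum simulation time, fs (required).
#' @param n_substeps Electronic substeps per nuclear step.
#' @param frustrated_reversal Velocity-reversal policy for frustrated hops.
#' @param decoherence `"none"` (default) or `"edc"`, an optional
#'   energy-based decoherence damping of the inactive amplitudes with time
#'   constant `hbar/|dE| (1 + C/Ekin)`, `C = 0.1` hartree-equivalent
#'   (2.72 eV).
#' @param s0_dwell_fs Terminate this long after reaching S0 (default `Inf`:
#'   run to `t_max_fs`).
#' @param seed Optional integer seed for the hop draws and thermostat.
#' @param record_amplitudes Stride (in steps) for storing `|c|^2` rows;
#'   `0` disables.
#' @return Object of class `hop_trajectory`: `times`, `surface_history`
#'   (0-based, one entry per recorded time), `hop_events` data frame,
#'   `energy_history` (total energy, eV), `amplitude_history`,
#'   `termination`, `t_max`, `final_state`.
#' @export
run_hopping_trajectory <- function(init, engines, config, t_max_fs,
                                   n_substeps = 20,
                                   frustrated_reversal = FALSE,
                                   decoherence = c("none", "edc"),
                                   s0_dwell_fs = Inf, seed = NULL,
                                   record_amplitudes = 0L) {
  decoherence <- match.arg(decoherence)
  stopifnot(inherits(config, "sampling_config"), t_max_fs > 0)
  model <- engines$model
  stopifnot(inherits(model, "model_surface"))
  if (!is.null(seed)) set.seed(seed)

  if (inherits(init, "initial_condition")) {
    state <- init$state
    surface <- init$start_surface
  } else {
    state <- init
    surface <- min(2L, model$n_states - 1L)
  }
  stopifnot(inherits(state, "phase_space_state"))
  if (is.null(state$partition))
    state$partition <- partition_system(length(state$positions),
                                        seq_len(model$n_dof))
  partition <- state$partition
  qm <- partition$qm_indices
  low <- if (is.null(engines$low_engine)) zero_engine()
         else engines$low_engine
  dt <- config$dt_hopping
  n_steps <- ceiling(t_max_fs / dt)
  n <- model$n_states

  cc <- complex(n)
  cc[surface + 1L] <- 1 + 0i
  amps <- electronic_amplitudes(cc, surface)

  # subtractive force on the occupied surface, reusing the already
  # diagonalized electronic structure for the high-level QM term
  total_force <- function(x, es, surf) {
    lf <- .eval_engine(low, x, "low level, full system")
    lq <- .eval_engine(low, x[qm], "low level, QM region")
    g <- lf$gradient
    g[qm] <- g[qm] - lq$gradient + es$gradients[surf + 1L, ]
    list(force = -g,
         energy = lf$energy - lq$energy + es$energies[surf + 1L])
  }

  es <- evaluate_surface(model, state$positions[qm])
  if (es$degenerate)
    warning("degenerate surfaces at the initial geometry")
  fr <- total_force(state$positions, es, surface)
  state$force <- fr$force
  state$potential_energy <- fr$energy

  times <- numeric(n_steps + 1L)
  surf_hist <- integer(n_steps + 1L)
  e_hist <- numeric(n_steps + 1L)
  amp_hist <- if (record_amplitudes > 0)
    matrix(NA_real_, n_steps %/% record_amplitudes + 1L, n) else NULL
  events <- list()
  times[1] <- state$time
  surf_hist[1] <- surface
  e_hist[1] <- fr$energy + .kinetic_energy_ev(state$velocities,
                                              state$masses)
  if (!is.null(amp_hist)) amp_hist[1, ] <- Mod(amps$c)^2

  t_s0 <- NA_real_
  termination <- "t_max"
  last <- n_steps + 1L
  for (step in seq_len(n_steps)) {
    a_acc <- state$force * .EV_MECH / state$masses
    x_new <- state$positions + state$velocities * dt + 0.5 * a_acc * dt^2
    es_new <- .align_nac(evaluate_surface(model, x_new[qm]), es)
    fr_new <- total_force(x_new, es_new, surface)
    if (!all(is.finite(fr_new$force)))
      stop("non-finite force at t = ", format(state$time + dt), " fs")
    a_new <- fr_new$force * .EV_MECH / state$masses
    v_new <- state$velocities + 0.5 * (a_acc + a_new) * dt

    snap_t <- coupling_snapshot(es, state$velocities[qm])
    state$positions <- x_new
    state$velocities <- v_new
    state$force <- fr_new$force
    state$potential_energy <- fr_new$energy
    state$time <- state$time + dt
    snap_new <- coupling_snapshot(es_new, v_new[qm])

    amps <- propagate_amplitudes(amps, snap_t, snap_new, dt, n_substeps)
    if (decoherence == "edc")
      amps <- .edc_damp(amps, es_new$energies,
                        .kinetic_energy_ev(v_new[qm], state$masses[qm]),
                        dt)

    g <- hop_probabilities(amps, snap_new, dt)
    hop <- attempt_hop(g, state, snap_new, amps, frustrated_reversal)
    state <- hop$state
    if (!is.null(hop$event)) events[[length(events) + 1L]] <- hop$event
    if (hop$new_surface != surface) {
      surface <- hop$new_surface
      amps$current_surface <- surface
      # forces now come from the new surface
      fr_new <- total_force(state$positions, es_new, surface)
      state$force <- fr_new$force
      state$potential_energy <- fr_new$energy
    }

    if (config$collision_frequency > 0 &&
        length(partition$mm_indices) > 0) {
      state <- andersen_thermostat(state, partition$mm_indices,
                                   config$temperature,
                                   config$collision_frequency, dt)
    }

    es <- es_new
    times[step + 1L] <- state$time
    surf_hist[step + 1L] <- surface
    e_hist[step + 1L] <- state$potential_energy +
      .kinetic_energy_ev(state$velocities, state$masses)
    if (!is.null(amp_hist) && step %% record_amplitudes == 0L)
      amp_hist[step %/% record_amplitudes + 1L, ] <- Mod(amps$c)^2

    if (surface == 0L && is.na(t_s0)) t_s0 <- state$time
    if (surface != 0L) t_s0 <- NA_real_
    if (!is.na(t_s0) && state$time - t_s0 >= s0_dwell_fs) {
      termination <- "s0_quiescence"
      last <- step + 1L
      break
    }
  }

  structure(list(
    times = times[seq_len(last)],
    surface_history = surf_hist[seq_len(last)],
    hop_events = if (length(events) > 0) do.call(rbind, events)
                 else data.frame(time = numeric(0), from = integer(0),
                                 to = integer(0), accepted = logical(0),
                                 frustrated = logical(0)),
    energy_history = e_hist[seq_len(last)],
    amplitude_history = amp_hist,
    n_renorm = amps$n_renorm,
    termination = termination,
    t_max = t_max_fs,
    final_state = state
  ), class = "hop_trajectory")
}

# energy-based decoherence damping (optional, off by default): inactive
# amplitudes decay with tau = hbar/|dE| (1 + C/Ekin), then the active one
# is rescaled to restore the norm
.edc_damp <- function(amps, energies, ekin_ev, dt, C = 2.7211) {
  a <- amps$current_surface + 1L
  n <- length(amps$c)
  for (b in seq_len(n)) {
    if (b == a) next
    de <- abs(energies[b] - energies[a])
    if (de < 1e-12) next
    tau <- .HBAR_EVFS / de * (1 + C / max(ekin_ev, 1e-8))
    amps$c[b] <- amps$c[b] * exp(-dt / tau)
  }
  pa_other <- sum(Mod(amps$c[-a])^2)
  pa <- Mod(amps$c[a])^2
  if (pa > 0)
    amps$c[a] <- amps$c[a] * sqrt(max(0, 1 - pa_other) / pa)
  amps
}
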