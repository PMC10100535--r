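#' Sample hop times from the sequential decay process
#'
#' Draws per-trajectory transition times of the two-step decay
#' S2 -> S1 -> S0 directly from its generating stochastic process:
#' `t_hop_21 ~ Exp(mean = tau2)` and
#' `t_hop_10 = t_hop_21 + Exp(mean = tau1)`.  The ensemble state occupancies
#' of this process solve the sequential kinetic rate equations exactly (see
#' [kinetic_model_solution()]), which makes the sampler the reference input
#' for testing the fitting stage in isolation from the dynamics.
#'
#' Times beyond the simulation horizon `t_max_fs` are recorded as `NA`
#' (the trajectory is still in the corresponding upper state when the run
#' ends), mirroring trajectories that reach the maximum simulation time.
#'
#' @param tau2_fs Mean S2 lifetime in fs.
#' @param tau1_ps Mean S1 lifetime in ps.
#' @param n_traj Number of trajectories (>= 1).
#' @param t_max_fs Simulation horizon in fs.
#' @param seed Optional integer seed.
#' @return A data frame of class `hop_times` with columns `trajectory_id`,
#'   `t_hop_21`, `t_hop_10` (fs, `NA` when beyond the horizon) and `t_max`.
#' @export
#' @examples
#' ht <- sample_hop_times(9.5, 0.83, 190, 20000, seed = 1)
#' mean(ht$t_hop_21, na.rm = TRUE)   # close to 9.5 fs
sample_hop_times <- function(tau2_fs, tau1_ps, n_traj, t_max_fs,
                             seed = NULL) {
  stopifnot(tau2_fs > 0, tau1_ps > 0, t_max_fs > 0, n_traj >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_traj <- as.integer(n_traj)
  tau1_fs <- tau1_ps * 1000

  t21 <- stats::rexp(n_traj, rate = 1 / tau2_fs)
  t10 <- t21 + stats::rexp(n_traj, rate = 1 / tau1_fs)
  t10[t10 > t_max_fs] <- NA_real_
  t21[t21 > t_max_fs] <- NA_real_
  t10[is.na(t21)] <- NA_real_

  structure(
    data.frame(trajectory_id = seq_len(n_traj),
               t_hop_21 = t21, t_hop_10 = t10, t_max = t_max_fs),
    class = c("hop_times", "data.frame"))
}
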