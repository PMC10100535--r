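#' Normalized swarm state occupancies
#'
#' Turns an ensemble of trajectories into normalized occupancy curves
#' `S_x(t)`: the fraction of trajectories occupying each electronic state at
#' every grid time.  Accepts either a `hop_times` frame from
#' [sample_hop_times()] (trajectories without a recorded transition stay in
#' the upper state for the whole horizon) or a list of `hop_trajectory`
#' objects (state read off the recorded surface history as a step
#' function).  The curves satisfy `s2 + s1 + s0 = 1` exactly at every grid
#' point, with `s2(0) = 1, s1(0) = 0` for swarms started on the second
#' excited state.
#'
#' @param trajectories A `hop_times` data frame or list of
#'   `hop_trajectory`.
#' @param grid Time grid in fs; defaults to 20001 evenly spaced points over
#'   the horizon (fine enough to resolve few-fs decays at ps horizons).
#' @return Object of class `swarm_populations`: `times`, `s2`, `s1`, `s0`,
#'   `n_traj`.
#' @export
normalized_occupancies <- function(trajectories, grid = NULL) {
  if (inherits(trajectories, "hop_times")) {
    n <- nrow(trajectories)
    if (n == 0) stop("empty trajectory set")
    t_max <- trajectories$t_max[1]
    if (is.null(grid)) grid <- seq(0, t_max, length.out = 20001)
    t21 <- trajectories$t_hop_21
    t10 <- trajectories$t_hop_10
    t21[is.na(t21)] <- Inf
    t10[is.na(t10)] <- Inf
    # survival functions of the two transition times give the occupancies
    s2 <- 1 - stats::ecdf(t21)(grid)
    s21 <- 1 - stats::ecdf(t10)(grid)     # fraction still in S2 or S1
    s1 <- s21 - s2
    s0 <- 1 - s21
  } else if (is.list(trajectories) && length(trajectories) > 0 &&
             inherits(trajectories[[1]], "hop_trajectory")) {
    n <- length(trajectories)
    t_max <- max(vapply(trajectories, function(tr) tr$t_max, 0))
    if (is.null(grid)) grid <- seq(0, t_max, length.out = 20001)
    n_states <- max(vapply(trajectories,
                           function(tr) max(tr$surface_history), 0L)) + 1L
    counts <- matrix(0, length(grid), max(n_states, 3L))
    for (tr in trajectories) {
      idx <- findInterval(grid, tr$times, rightmost.closed = FALSE)
      idx[idx == 0L] <- 1L            # grid point before first record
      surf <- tr$surface_history[pmin(idx, length(tr$surface_history))]
      for (s in unique(surf))
        counts[, s + 1L] <- counts[, s + 1L] + (surf == s)
    }
    occ <- counts / n
    s0 <- occ[, 1]
    s1 <- occ[, 2]
    s2 <- if (ncol(occ) >= 3) occ[, 3] else rep(0, length(grid))
    # enforce the partition exactly (guards higher states, none expected)
    s0 <- 1 - s1 - s2
  } else {
    stop("trajectories must be a 'hop_times' frame or a non-empty list ",
         "of 'hop_trajectory' objects")
  }
  structure(list(times = grid, s2 = s2, s1 = s1, s0 = s0, n_traj = n),
            class = "swarm_populations")
}

#' Closed-form sequential decay kinetics
#'
#' Solution of the two-step first-order decay S2 -> S1 -> S0,
#' `dS2/dt = -S2/tau2`, `dS1/dt = S2/tau2 - S1/tau1`, `S0 = 1 - S1 - S2`,
#' with initial conditions `S2(0) = 1`, `S1(0) = 0`:
#' `s2 = exp(-t/tau2)`,
#' `s1 = tau1/(tau1 - tau2) (exp(-t/tau1) - exp(-t/tau2))`,
#' switching to the equal-lifetime limit `s1 = (t/tau) exp(-t/tau)` when
#' the lifetimes coincide to relative 1e-8.
#'
#' @param tau2_fs,tau1_fs Lifetimes in fs (> 0).
#' @param t Time or time vector in fs.
#' @return List with numeric vectors `s2`, `s1`, `s0`.
#' @export
#' @examples
#' kinetic_model_solution(9.5, 830, 2000)$s0   # ground-state fraction at 2 ps
kinetic_model_solution <- function(tau2_fs, tau1_fs, t) {
  if (!(tau2_fs > 0) || !(tau1_fs > 0))
    stop("lifetimes must be positive")
  s2 <- exp(-t / tau2_fs)
  if (abs(tau1_fs - tau2_fs) <= 1e-8 * max(tau1_fs, tau2_fs)) {
    s1 <- (t / tau1_fs) * exp(-t / tau1_fs)
  } else {
    s1 <- tau1_fs / (tau1_fs - tau2_fs) * (exp(-t / tau1_fs) - s2)
  }
  list(s2 = s2, s1 = s1, s0 = 1 - s1 - s2)
}

#' Fit excited-state lifetimes to swarm occupancies
#'
#' Joint unweighted nonlinear least squares of the `s2` and `s1` occupancy
#' curves against [kinetic_model_solution()], over `(tau2, tau1)`
#' parameterized on the log scale for positivity (Levenberg-Marquardt,
#' `minpack.lm`).  `s0` is excluded as redundant under the partition of
#' unity.  Starting values are deterministic: `tau2` from the first time
#' `s2` drops below `1/e`, `tau1` from the 1/e point of the `s1` tail after
#' its peak.
#'
#' @param populations A `swarm_populations`.
#' @param start Optional named vector `c(tau2_fs =, tau1_fs =)` overriding
#'   the automatic starting values.
#' @return Object of class `lifetime_fit`: `tau2_fs`, `tau1_ps`,
#'   `sigma_tau2_fs`, `sigma_tau1_ps` (`NA` until
#'   [subset_error_extrapolation()] fills them), `fit_residual` (sum of
#'   squares), `n_traj`, `converged`, `start`.
#' @export
fit_lifetimes <- function(populations, start = NULL) {
  stopifnot(inherits(populations, "swarm_populations"))
  t <- populations$times
  if (max(populations$s2) < 1e-12) {
    # two-state swarm: the tau2 -> 0 limit, single-exponential s1 decay
    if (min(populations$s1) >= 1 - 1e-12)
      # no decay observed over the horizon: the lifetime is unbounded
      return(structure(list(tau2_fs = NA_real_, tau1_ps = Inf,
                            sigma_tau2_fs = NA_real_,
                            sigma_tau1_ps = NA_real_, fit_residual = 0,
                            n_traj = populations$n_traj, converged = TRUE,
                            start = NULL),
                       class = "lifetime_fit"))
    resid1 <- function(p) exp(-t / exp(p)) - populations$s1
    i1 <- which(populations$s1 < exp(-1))[1]
    p0 <- log(if (is.na(i1) || t[i1] <= 0) max(t) / 3 else t[i1])
    fit <- minpack.lm::nls.lm(par = p0, fn = resid1,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-14, ptol = 1e-12))
    if (!(fit$info %in% 1:4))
      stop("single-exponential lifetime fit did not converge (info = ",
           fit$info, ")")
    return(structure(list(tau2_fs = NA_real_, tau1_ps = exp(fit$par) / 1000,
                          sigma_tau2_fs = NA_real_,
                          sigma_tau1_ps = NA_real_,
                          fit_residual = fit$deviance,
                          n_traj = populations$n_traj, converged = TRUE,
                          start = c(tau1_fs = exp(p0))),
                     class = "lifetime_fit"))
  }
  if (min(populations$s2) > exp(-1) * 1.5)
    warning("s2 has barely decayed over the grid; tau2 poorly determined")

  if (is.null(start)) start <- .lifetime_start(populations)
  par0 <- log(c(start[["tau2_fs"]], start[["tau1_fs"]]))

  resid_fn <- function(p) {
    k <- kinetic_model_solution(exp(p[1]), exp(p[2]), t)
    c(k$s2 - populations$s2, k$s1 - populations$s1)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-12))
  if (!(fit$info %in% 1:4))
    stop("lifetime fit did not converge (info = ", fit$info, ", message: ",
         fit$message, "); starting values tau2 = ", start[["tau2_fs"]],
         " fs, tau1 = ", start[["tau1_fs"]], " fs; residual trace: ",
         paste(format(utils::tail(fit$rsstrace, 5), digits = 6),
               collapse = " "))
  tau <- exp(fit$par)
  structure(list(tau2_fs = tau[1], tau1_ps = tau[2] / 1000,
                 sigma_tau2_fs = NA_real_, sigma_tau1_ps = NA_real_,
                 fit_residual = fit$deviance, n_traj = populations$n_traj,
                 converged = TRUE, start = start),
            class = "lifetime_fit")
}

.lifetime_start <- function(populations) {
  t <- populations$times
  i2 <- which(populations$s2 < exp(-1))[1]
  tau2 <- if (is.na(i2) || t[i2] <= 0) max(t) / 2 else t[i2]
  ip <- which.max(populations$s1)
  tail1 <- which(populations$s1 < populations$s1[ip] / exp(1) &
                   seq_along(t) > ip)[1]
  tau1 <- if (is.na(tail1)) max(t) / 3 else t[tail1] - t[ip]
  if (tau1 <= 0) tau1 <- max(t) / 3
  c(tau2_fs = tau2, tau1_fs = tau1)
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf(
    "Sequential-decay lifetime fit (n = %d trajectories)\n", x$n_traj))
  cat(sprintf("  tau2 = %.3g fs (sigma %.3g fs)\n", x$tau2_fs,
              x$sigma_tau2_fs))
  cat(sprintf("  tau1 = %.3g ps (sigma %.3g ps)\n", x$tau1_ps,
              x$sigma_tau1_ps))
  cat(sprintf("  residual sum of squares = %.4g\n", x$fit_residual))
  invisible(x)
}

#' Reshuffled-subset 1/N extrapolation of lifetime standard errors
#'
#' The direct covariance of the occupancy fit underestimates the swarm
#' sampling error, so the spread is estimated from subsets: the trajectory
#' set is reshuffled and divided into halves, thirds, quarters, ... while
#' more than `min_subset` trajectories remain per part; each part is fitted,
#' and the standard deviation of the fitted lifetimes across the parts is
#' recorded.  Reshuffling repeats `n_reshuffles` times per level and the
#' per-level spreads are averaged.  The averaged spreads are then fitted by
#' least squares as a line in 1/N (N = trajectories per subset) and
#' evaluated at the full-swarm N to give the reported standard deviations.
#' A `1/sqrt(N)` abscissa (the conventional standard-error scaling) is
#' available via `abscissa`.
#'
#' @param trajectories A `hop_times` frame or list of `hop_trajectory`.
#' @param fit_fn Function mapping a trajectory subset to
#'   `c(tau2_fs, tau1_fs)`; defaults to [normalized_occupancies()] +
#'   [fit_lifetimes()].
#' @param n_reshuffles Reshuffles per division level (default 10).
#' @param min_subset Subsets must keep more than this many trajectories
#'   (default 30).
#' @param abscissa `"1/N"` (default) or `"1/sqrtN"`.
#' @param seed Optional integer seed for the reshuffles.
#' @return List: `sigma_tau2_fs`, `sigma_tau1_ps`, `levels` (data frame of
#'   per-level spreads), `n_traj`.
#' @export
subset_error_extrapolation <- function(trajectories, fit_fn = NULL,
                                       n_reshuffles = 10, min_subset = 30,
                                       abscissa = c("1/N", "1/sqrtN"),
                                       seed = NULL) {
  abscissa <- match.arg(abscissa)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.data.frame(trajectories)) nrow(trajectories)
       else length(trajectories)
  take <- function(idx) {
    if (is.data.frame(trajectories)) trajectories[idx, , drop = FALSE]
    else trajectories[idx]
  }
  if (is.null(fit_fn))
    fit_fn <- function(sub) {
      ft <- fit_lifetimes(normalized_occupancies(sub))
      c(ft$tau2_fs, ft$tau1_ps * 1000)
    }

  ks <- integer(0)
  k <- 2L
  while (n %/% k > min_subset) {
    ks <- c(ks, k)
    k <- k + 1L
  }
  if (length(ks) < 2)
    stop("need at least 2 division levels with more than ", min_subset,
         " trajectories per part (have n = ", n, "); no extrapolation ",
         "possible")

  levels <- data.frame(k = ks, N = n / ks, sigma_tau2 = NA_real_,
                       sigma_tau1 = NA_real_)
  for (li in seq_along(ks)) {
    k <- ks[li]
    sp2 <- sp1 <- numeric(0)
    for (r in seq_len(n_reshuffles)) {
      perm <- sample.int(n)                     # reshuffle before division
      lab <- sort(rep(seq_len(k), length.out = n))  # near-equal blocks
      fits <- matrix(NA_real_, k, 2)
      for (j in seq_len(k)) {
        sub <- take(perm[lab == j])
        fits[j, ] <- tryCatch(fit_fn(sub),
                              error = function(e) c(NA_real_, NA_real_))
      }
      ok <- stats::complete.cases(fits)
      if (sum(ok) >= 2) {
        sp2 <- c(sp2, stats::sd(fits[ok, 1]))
        sp1 <- c(sp1, stats::sd(fits[ok, 2]))
      }
    }
    levels$sigma_tau2[li] <- mean(sp2)
    levels$sigma_tau1[li] <- mean(sp1)
  }

  x <- if (abscissa == "1/N") 1 / levels$N else 1 / sqrt(levels$N)
  x_full <- if (abscissa == "1/N") 1 / n else 1 / sqrt(n)
  extrap <- function(y) {
    cf <- stats::coef(stats::lm(y ~ x))
    max(0, unname(cf[1] + cf[2] * x_full))
  }
  list(sigma_tau2_fs = extrap(levels$sigma_tau2),
       sigma_tau1_ps = extrap(levels$sigma_tau1) / 1000,
       levels = levels, n_traj = n, abscissa = abscissa)
}

#' Internal-consistency record of a trajectory swarm
#'
#' FSSH only approximately equates ensemble surface populations with the
#' mean electronic populations `|c_a|^2`; this helper tabulates both for
#' inspection (reported, never asserted as exact).  Requires trajectories
#' run with `record_amplitudes > 0`.
#'
#' @param trajectories List of `hop_trajectory` with amplitude records.
#' @return Data frame with per-recorded-step surface populations and mean
#'   electronic populations.
#' @export
swarm_consistency <- function(trajectories) {
  keep <- Filter(function(tr) !is.null(tr$amplitude_history), trajectories)
  if (length(keep) == 0)
    stop("no trajectories carry amplitude records ",
         "(run with record_amplitudes > 0)")
  n_rows <- min(vapply(keep, function(tr) nrow(tr$amplitude_history), 0L))
  n_states <- ncol(keep[[1]]$amplitude_history)
  mean_pop <- Reduce(`+`, lapply(keep, function(tr)
    tr$amplitude_history[seq_len(n_rows), , drop = FALSE])) / length(keep)
  surf <- vapply(keep, function(tr) {
    stride <- (length(tr$surface_history) - 1L) %/% max(1L, n_rows - 1L)
    tr$surface_history[1L + stride * (seq_len(n_rows) - 1L)]
  }, integer(n_rows))
  surf_pop <- t(vapply(seq_len(n_states) - 1L, function(s)
    rowMeans(matrix(surf == s, nrow = n_rows)), numeric(n_rows)))
  out <- data.frame(row = seq_len(n_rows))
  for (s in seq_len(n_states)) {
    out[[paste0("surface_S", s - 1L)]] <- surf_pop[s, ]
    out[[paste0("electronic_S", s - 1L)]] <- mean_pop[, s]
  }
  out
}
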