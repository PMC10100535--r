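#' Assemble and validate a pipeline configuration
#'
#' Builds the full run configuration with documented defaults, merged with
#' user overrides (a nested list or a YAML file path).  One master seed
#' spawns a named child stream per stochastic stage (bath construction,
#' ground-state run, swarm draw, each hopping trajectory by id, error
#' resampling), so enlarging the swarm never perturbs existing
#' trajectories.
#'
#' @param config A nested list of overrides, or a path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    model = list(n_states = 3L, params = NULL),
    bath = list(n_particles = 0L, temperature = 298,
                coupling_strength = 0.05),
    sampling = list(dt_ground = 0.5, dt_hopping = 0.1, t_ground_ps = 2,
                    temperature = 298, collision_frequency = 0.01,
                    stride = 10),
    selection = list(energy_window = c(-Inf, Inf),
                     strength_threshold = 0),
    swarm_size = 100L,
    t_max_fs = 500,
    hopping = list(n_substeps = 20L, frustrated_reversal = FALSE,
                   s0_dwell_fs = Inf, thermostat = FALSE),
    fit = list(n_reshuffles = 10L, min_subset = 30L, abscissa = "1/N"),
    output_dir = NULL,
    write_trajectories = FALSE
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$swarm_size) || cfg$swarm_size < 1)
    stop("swarm_size must be >= 1")
  if (!is.numeric(cfg$t_max_fs) || cfg$t_max_fs <= 0)
    stop("t_max_fs must be positive")
  if (!cfg$model$n_states %in% c(2, 3))
    stop("model$n_states must be 2 or 3")
  if (length(cfg$selection$energy_window) != 2)
    stop("selection$energy_window must be c(lo, hi)")
  structure(cfg, class = c("run_config", "list"))
}

# deterministic named child seed below 2^31
.child_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(master) %% 2147483647) * 2654435 %% 2147483647) %%
               2147483647)
}

#' Run the full excited-state lifetime pipeline
#'
#' Seeded end-to-end protocol: build the model surface and (optional)
#' surrogate bath, run thermostatted ground-state dynamics, select
#' initial conditions by the excitation-energy window and
#' transition-strength threshold, launch the fewest-switches hopping swarm
#' from the second excited state, accumulate normalized occupancies, fit
#' the sequential decay lifetimes, and extrapolate their standard errors
#' from reshuffled subsets.  Fully deterministic given the master seed.
#'
#' When `config$output_dir` is set, writes `populations.tsv`, `fit.tsv`
#' (Table-style column order: n_traj, tau2 fs, sigma fs, tau1 ps, sigma
#' ps), `manifest.yaml` (config, derived seeds, package and R versions),
#' and optionally per-trajectory extended-XYZ files.
#'
#' @param config A `run_config`, a nested override list, or a YAML path
#'   (see [pipeline_config()]).
#' @return List of class `pipeline_result`: `populations`
#'   (`swarm_populations`), `fit` (`lifetime_fit`, sigmas filled when the
#'   swarm supports extrapolation), `trajectories`, `initial_conditions`,
#'   `model`, `config`, `files`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config
         else pipeline_config(config)
  master <- cfg$seed

  model <- make_avoided_crossing_model(cfg$model$n_states,
                                       cfg$model$params)
  n_qm <- model$n_dof

  bath <- NULL
  low <- NULL
  if (cfg$bath$n_particles > 0) {
    bath <- make_solvent_bath(cfg$bath$n_particles, cfg$bath$temperature,
                              seed = .child_seed(master, "bath"),
                              coupling_strength = cfg$bath$coupling_strength)
    low <- bath_low_engine(bath, n_qm)
  }

  # initial full-system state: solute at the ground-diabat reference with
  # thermal velocities, bath appended row-wise
  set.seed(.child_seed(master, "init"))
  r0 <- model$states[[1]]$r0
  positions <- c(r0, if (!is.null(bath)) as.numeric(t(bath$positions)))
  masses <- c(model$masses,
              if (!is.null(bath)) rep(bath$masses, each = 3))
  velocities <- c(.mb_velocities(model$masses, cfg$sampling$temperature),
                  if (!is.null(bath)) as.numeric(t(bath$velocities)))
  partition <- partition_system(length(positions), seq_len(n_qm))
  state0 <- phase_space_state(positions, velocities, masses,
                              partition = partition)

  samp <- sampling_config(
    dt_ground = cfg$sampling$dt_ground,
    dt_hopping = cfg$sampling$dt_hopping,
    t_ground_ps = cfg$sampling$t_ground_ps,
    temperature = cfg$sampling$temperature,
    collision_frequency = cfg$sampling$collision_frequency,
    stride = cfg$sampling$stride,
    seed = .child_seed(master, "ground"))

  engines <- list(model = model, low_engine = low)
  snapshots <- run_ground_state_md(state0, engines, samp)
  if (length(snapshots) == 0)
    stop("pipeline stage 'sample' produced no snapshots")

  ics <- select_initial_conditions(snapshots, cfg$selection$energy_window,
                                   cfg$selection$strength_threshold)
  if (length(ics) == 0)
    stop("pipeline stage 'select': no initial conditions passed the ",
         "selection criteria")
  set.seed(.child_seed(master, "swarm"))
  pick <- if (length(ics) >= cfg$swarm_size)
    sample(length(ics), cfg$swarm_size)
  else sample(length(ics), cfg$swarm_size, replace = TRUE)

  hop_cfg <- samp
  hop_cfg$collision_frequency <- if (isTRUE(cfg$hopping$thermostat))
    cfg$sampling$collision_frequency else 0

  trajectories <- vector("list", cfg$swarm_size)
  for (i in seq_len(cfg$swarm_size)) {
    trajectories[[i]] <- tryCatch(
      run_hopping_trajectory(
        ics[[pick[i]]], engines, hop_cfg, cfg$t_max_fs,
        n_substeps = cfg$hopping$n_substeps,
        frustrated_reversal = cfg$hopping$frustrated_reversal,
        s0_dwell_fs = cfg$hopping$s0_dwell_fs,
        seed = .child_seed(master, paste0("hop", i))),
      error = function(e)
        stop("pipeline stage 'hop' failed for trajectory ", i, ": ",
             conditionMessage(e), call. = FALSE))
  }

  populations <- normalized_occupancies(trajectories)
  fit <- fit_lifetimes(populations)
  err <- tryCatch(
    subset_error_extrapolation(trajectories,
                               n_reshuffles = cfg$fit$n_reshuffles,
                               min_subset = cfg$fit$min_subset,
                               abscissa = cfg$fit$abscissa,
                               seed = .child_seed(master, "errors")),
    error = function(e) NULL)
  if (!is.null(err)) {
    fit$sigma_tau2_fs <- err$sigma_tau2_fs
    fit$sigma_tau1_ps <- err$sigma_tau1_ps
  }

  files <- character(0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- .write_pipeline_artifacts(cfg, populations, fit, trajectories,
                                       master)
  }

  structure(list(populations = populations, fit = fit,
                 trajectories = trajectories, initial_conditions = ics,
                 model = model, config = cfg, files = files),
            class = "pipeline_result")
}

.write_pipeline_artifacts <- function(cfg, populations, fit, trajectories,
                                      master) {
  out <- cfg$output_dir
  pop_path <- file.path(out, "populations.tsv")
  pop <- data.frame(time_fs = populations$times, s2 = populations$s2,
                    s1 = populations$s1, s0 = populations$s0)
  utils::write.table(format(pop, digits = 12, trim = TRUE), pop_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fit_path <- file.path(out, "fit.tsv")
  ft <- data.frame(n_traj = fit$n_traj, tau2_fs = fit$tau2_fs,
                   sigma_tau2_fs = fit$sigma_tau2_fs,
                   tau1_ps = fit$tau1_ps,
                   sigma_tau1_ps = fit$sigma_tau1_ps)
  utils::write.table(format(ft, digits = 8, trim = TRUE), fit_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  man_path <- file.path(out, "manifest.yaml")
  yaml::write_yaml(list(
    package = "surfhop",
    package_version = as.character(utils::packageVersion("surfhop")),
    r_version = as.character(getRversion()),
    master_seed = master,
    child_seeds = list(bath = .child_seed(master, "bath"),
                       init = .child_seed(master, "init"),
                       ground = .child_seed(master, "ground"),
                       swarm = .child_seed(master, "swarm"),
                       errors = .child_seed(master, "errors")),
    config = .manifest_sanitize(unclass(cfg))), man_path)

  files <- c(pop_path, fit_path, man_path)
  if (isTRUE(cfg$write_trajectories)) {
    for (i in seq_along(trajectories)) {
      p <- file.path(out, sprintf("trajectory_%03d.xyz", i))
      tr <- trajectories[[i]]
      write_xyz(list(state_to_frame(tr$final_state,
                                    info = list(surface = tr$surface_history[length(tr$surface_history)]))),
                p)
      files <- c(files, p)
    }
  }
  files
}

.manifest_sanitize <- function(x) {
  rapply(x, function(v) {
    if (is.numeric(v)) ifelse(is.infinite(v),
                              ifelse(v > 0, ".inf", "-.inf"), v)
    else v
  }, how = "replace")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Surface-hopping pipeline result\n")
  cat("  swarm size:", length(x$trajectories), "trajectories, horizon",
      x$config$t_max_fs, "fs\n")
  n_end <- sum(vapply(x$trajectories, function(tr)
    tr$surface_history[length(tr$surface_history)] == 0L, TRUE))
  cat("  trajectories ending in S0:", n_end, "\n")
  print(x$fit)
  invisible(x)
}
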