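#' Registered scenarios
#'
#' The scenario registry maps short names onto fully parameterised runs of
#' the package's models, each writing deterministic CSV/JSON artifacts:
#'
#' * `fig3` — default two-pool plane-wave superposition and its power
#'   spectrum (signaling pool 250 arb units at 150 Hz, pumping pool 500 at
#'   500 Hz).
#' * `fig4` — same field after an ouabain-induced E2:E1 shift (default 5%)
#'   applied to the signaling pool amplitude.
#' * `fig6_basal` — calibrated oxidant-loop run with no perturbation.
#' * `fig6_ouabain` — calibrated loop with 100 uM ouabain (about 10% of
#'   the IC50) added at t = 2500.
#' * `thermo_demo` — 3-state kinetic cycle with k+ = (2,2,2),
#'   k- = (1,1,1): NESS flux, entropy production and a relaxation
#'   trajectory.
#' * `markov_demo` — illustrative Post-Albers one-step matrix: validation,
#'   stationary distribution and a seeded sample path.
#'
#' @return Tibble with columns `name`, `module`, `description`.
#' @export
scenario_registry <- function() {
  tibble(
    name = c("fig3", "fig4", "fig6_basal", "fig6_ouabain",
             "thermo_demo", "markov_demo"),
    module = c("superposition", "superposition", "ros_loop", "ros_loop",
               "master_thermo", "markov_core"),
    description = c(
      "two-pool plane-wave field and power spectrum",
      "ouabain-shifted field (signaling amplitude scaled) and spectrum",
      "calibrated oxidant loop, no perturbation",
      "calibrated oxidant loop, 100 uM ouabain at t = 2500",
      "3-cycle NESS flux, entropy production, relaxation",
      "Post-Albers chain: stationary distribution and sample path"
    )
  )
}

#' Run a registered scenario
#'
#' Executes a scenario end-to-end and writes its artifacts under
#' `out_prefix`; a JSON manifest lists every file with its MD5 checksum,
#' so identical invocations of the deterministic scenarios produce
#' identical checksums.
#'
#' @param name Registered scenario name (see [scenario_registry()]).
#' @param overrides Named list of scenario parameters to override.
#'   Recognised keys: `shift` (fig4, default 0.05), `duration`,
#'   `sample_rate`, `dx` (wave scenarios); `ouabain_conc`, `onset_time`,
#'   `t_max`, `dt_out`, `target_e1` and any [loop_params()] field (loop
#'   scenarios); `k_plus`, `k_minus`, `t_max` (thermo); `n_steps`, `seed`
#'   (markov).
#' @param out_prefix Path prefix for output files (directories are
#'   created).
#' @param seed Seed threaded to stochastic components (only the Markov
#'   path sampler is stochastic).
#' @return Invisibly, the manifest tibble (`file`, `md5`); also written as
#'   `<out_prefix>_manifest.json`.
#' @export
run_scenario <- function(name, overrides = list(), out_prefix = "pumploop",
                         seed = 1L) {
  reg <- scenario_registry()
  if (!name %in% reg$name) {
    abort(paste0("unknown scenario '", name, "'; registered: ",
                 paste(reg$name, collapse = ", ")),
          class = "pumploop_argument_error")
  }
  known <- scenario_override_keys(name)
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    abort(paste0("invalid override(s) for ", name, ": ",
                 paste(bad, collapse = ", "),
                 "; allowed: ", paste(known, collapse = ", ")),
          class = "pumploop_argument_error")
  }
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- switch(
    name,
    fig3 = run_wave_scenario(overrides, out_prefix, shift = 0),
    fig4 = run_wave_scenario(overrides, out_prefix, shift = 0.05),
    fig6_basal = run_loop_scenario(overrides, out_prefix, perturbed = FALSE),
    fig6_ouabain = run_loop_scenario(overrides, out_prefix, perturbed = TRUE),
    thermo_demo = run_thermo_scenario(overrides, out_prefix),
    markov_demo = run_markov_scenario(overrides, out_prefix, seed = seed)
  )
  manifest <- tibble(file = files, md5 = unname(tools::md5sum(files)))
  manifest_path <- paste0(out_prefix, "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

scenario_override_keys <- function(name) {
  switch(
    name,
    fig3 = c("duration", "sample_rate", "dx", "n_peaks"),
    fig4 = c("shift", "duration", "sample_rate", "dx", "n_peaks"),
    fig6_basal = ,
    fig6_ouabain = c("ouabain_conc", "onset_time", "t_max", "dt_out",
                     "target_e1", names(loop_params())),
    thermo_demo = c("k_plus", "k_minus", "t_max"),
    markov_demo = c("n_steps", "seed")
  )
}

run_wave_scenario <- function(ov, out_prefix, shift) {
  shift <- ov$shift %||% shift
  pools <- apply_ouabain_shift(default_pools(), shift)
  field <- build_field(pools,
                       duration = ov$duration %||% 1,
                       sample_rate = ov$sample_rate %||% 4096,
                       dx = ov$dx %||% 1)
  spec <- power_spectrum(field)
  peaks <- suppressWarnings(peak_locations(spec, n_peaks = ov$n_peaks %||% 2))
  spec_path <- paste0(out_prefix, "_spectrum.csv")
  write_spectrum(spec, spec_path)
  peaks_path <- paste0(out_prefix, "_peaks.csv")
  write.csv(as.data.frame(peaks), peaks_path, quote = FALSE, row.names = FALSE)
  c(spec_path, peaks_path)
}

run_loop_scenario <- function(ov, out_prefix, perturbed) {
  par_keys <- intersect(names(ov), names(loop_params()))
  params <- do.call(loop_params, ov[par_keys])
  params <- calibrate_basal(params, target_e1 = ov$target_e1 %||% 0.5)
  pert <- if (perturbed) {
    perturbation("ouabain",
                 onset_time = ov$onset_time %||% 2500,
                 magnitude = ov$ouabain_conc %||% 100)
  }
  traj <- simulate_loop(params, perturbations = pert,
                        t_max = ov$t_max %||% 5000,
                        dt_out = ov$dt_out %||% 1)
  traj_path <- paste0(out_prefix, "_trajectory.csv")
  write_trajectory(traj, traj_path)
  metrics_path <- paste0(out_prefix, "_metrics.json")
  jsonlite::write_json(as.list(loop_metrics(traj)), metrics_path,
                       auto_unbox = TRUE, digits = NA)
  c(traj_path, metrics_path)
}

run_thermo_scenario <- function(ov, out_prefix) {
  rates <- rate_set(ov$k_plus %||% c(2, 2, 2), ov$k_minus %||% c(1, 1, 1))
  thermo <- entropy_production(rates)
  n <- length(rates$k_plus)
  p0 <- c(1, rep(0, n - 1))
  t_max <- ov$t_max %||% 10
  traj <- integrate_master(p0, rates, seq(0, t_max, length.out = 101))
  thermo_path <- paste0(out_prefix, "_thermo.json")
  jsonlite::write_json(as.list(as_tibble(thermo)), thermo_path,
                       auto_unbox = TRUE, digits = NA)
  traj_path <- paste0(out_prefix, "_relaxation.csv")
  df <- as.data.frame(lapply(traj, function(v) sprintf("%.17g", v)))
  names(df) <- names(traj)
  write.csv(df, traj_path, quote = FALSE, row.names = FALSE)
  c(thermo_path, traj_path)
}

run_markov_scenario <- function(ov, out_prefix, seed) {
  P <- default_post_albers_matrix()
  pi <- stationary_distribution(P)
  path <- simulate_chain(P, n_steps = ov$n_steps %||% 1000,
                         seed = ov$seed %||% seed)
  matrix_path <- paste0(out_prefix, "_matrix.csv")
  write_transition_matrix(P, matrix_path)
  pi_path <- paste0(out_prefix, "_stationary.csv")
  df <- data.frame(state = pi$state, pi = sprintf("%.17g", pi$pi))
  write.csv(df, pi_path, quote = FALSE, row.names = FALSE)
  path_path <- paste0(out_prefix, "_path.csv")
  write.csv(data.frame(step = path$step, state = as.character(path$state)),
            path_path, quote = FALSE, row.names = FALSE)
  c(matrix_path, pi_path, path_path)
}

#' Generate the package's example fixtures
#'
#' Writes small, seeded, reproducible input files exercised by the test
#' suite and the command-line front-end: the illustrative Post-Albers
#' transition matrix, a random irreducible stochastic matrix, a driven
#' 3-cycle rate set and a detailed-balance rate set, the default pool
#' configuration and the default loop parameters.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @return Invisibly, the vector of written file paths.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create fixture directory ", out_dir),
          class = "pumploop_io_error")
  }
  set.seed(as.integer(seed))
  files <- character()
  p1 <- file.path(out_dir, "post_albers_matrix.csv")
  write_transition_matrix(default_post_albers_matrix(), p1)
  M <- random_stochastic_matrix(5)
  p2 <- file.path(out_dir, "random_matrix.csv")
  write_transition_matrix(transition_matrix(M), p2)
  p3 <- file.path(out_dir, "cycle_rates_driven.csv")
  write_rate_set(rate_set(c(2, 2, 2), c(1, 1, 1)), p3)
  kp <- runif(4, 0.5, 2)
  p4 <- file.path(out_dir, "cycle_rates_detailed_balance.csv")
  write_rate_set(rate_set(kp, kp), p4)
  p5 <- file.path(out_dir, "pools.csv")
  write.csv(as.data.frame(default_pools()), p5, quote = FALSE, row.names = FALSE)
  p6 <- file.path(out_dir, "loop_params.json")
  lp <- loop_params()
  jsonlite::write_json(lp[names(lp)], p6, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4, p5, p6))
}

# Dirichlet-like random row-stochastic matrix; strictly positive entries,
# hence irreducible and aperiodic
random_stochastic_matrix <- function(n) {
  M <- matrix(-log(runif(n * n)), n, n)
  M / rowSums(M)
}
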