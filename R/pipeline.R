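# End-to-end pipeline: simulate -> (noise) -> estimate -> classify, driven
# by one flat configuration and one seed. Every artifact is reproducible
# from (config, seed) alone; each stage derives its own RNG stream so
# stages can be rerun independently.

config_recording <- function(cfg) {
  recording_spec(frame_rate = cfg$frame_rate, duration = cfg$duration_s,
                 field_xy = c(cfg$field_x_um, cfg$field_y_um),
                 chamber_depth = cfg$chamber_depth_um,
                 sigma_xy = cfg$sigma_xy_um, sigma_z = cfg$sigma_z_um,
                 drift_xy = c(cfg$drift_x_um_s, cfg$drift_y_um_s))
}

config_environment <- function(cfg) {
  mission_environment(cfg$environment,
                      fluid = water_medium(cfg$temperature_K))
}

config_size_model <- function(cfg) {
  switch(cfg$size_model,
    fixed = size_fixed(cfg$radius_um),
    lognormal = size_lognormal(cfg$radius_um, cfg$size_sigma),
    cluster = size_cluster(cfg$monomer_diameter_um, cfg$max_multiplicity),
    abort(sprintf("Unknown size_model '%s'.", cfg$size_model)))
}

#' Run the whole simulate-estimate-classify pipeline
#'
#' Simulates a ground-truthed population under the configured recording
#' and environment, applies localization noise, estimates per-particle
#' size/density/Strouhal, filters diffusivity outliers, classifies against
#' the density gap, and (when `out_dir` is given) writes the tracks,
#' truth, estimates and classification CSVs plus a JSON summary.
#'
#' @param config Named list as from [default_config()] / [read_config()].
#' @param out_dir Output directory for artifacts; `NULL` writes nothing.
#' @param seed Overrides `config$seed` when non-NULL.
#' @return List: `tracks`, `truth`, `estimates`, `classifications`,
#'   `confusion`, `summary`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  seed <- seed %||% cfg$seed
  env <- config_environment(cfg)
  rec <- config_recording(cfg)
  pop <- sample_population(
    population_spec(cfg$material, cfg$n_particles, config_size_model(cfg),
                    env),
    seed = seed)
  sim <- simulate_population(pop, rec, env, seed = seed, init = cfg$init)
  tracks <- apply_localization_noise(sim$tracks, rec, seed = seed)
  est <- estimate_particles(
    tracks, env,
    radius_source = cfg$radius_source,
    fixed_radius_um = if (is.na(cfg$fixed_radius_um)) NULL
                      else cfg$fixed_radius_um,
    dims = cfg$dims, max_lag = cfg$max_lag)
  est <- filter_outliers(est, "D_um2_s", cfg$outlier_D_cutoff_um2_s)
  cls <- classify_population(
    est, env$fluid,
    thresholds = c(cell = cfg$cell_threshold_kg_m3,
                   mineral = cfg$mineral_threshold_kg_m3),
    truth = sim$truth)
  summ <- dplyr::bind_rows(
    summarize_population(est, "D_um2_s"),
    summarize_population(est, "r_um"),
    summarize_population(est, "vz_um_s"),
    summarize_population(est, "delta_rho_kg_m3"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    write_truth(sim$truth, file.path(out_dir, "truth.csv"))
    write_estimates(est, file.path(out_dir, "estimates.csv"))
    write_classifications(cls, file.path(out_dir, "classifications.csv"))
    write_summary_json(summ, file.path(out_dir, "summary.json"))
  }
  list(tracks = tracks, truth = sim$truth, estimates = est,
       classifications = cls, confusion = confusion_matrix(cls),
       summary = summ)
}

# ---- command-line dispatcher ----------------------------------------------

.cli_flags <- function(args) {
  out <- list(); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      abort(sprintf("Expected a --flag, got '%s'.", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      val <- args[i + 1]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `detect`, `link`, `estimate`,
#' `classify`, `plan` and `run-all` over the package functions; see the
#' launcher script in `inst/cli/passivemotion.R` for shell use. Flags are
#' `--key value` pairs; config-file keys (`--config file.yml`) are
#' overridden by explicit flags. Artifacts are written to `--out`
#' (default `"."`).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly).
#' @examples
#' \donttest{
#' td <- tempfile(); dir.create(td)
#' pm_cli(c("plan", "--env", "Enceladus", "--out", td))
#' }
#' @export
pm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    abort(paste("Usage: <simulate|detect|link|estimate|classify|plan|run-all>",
                "[--flags]"))
  sub <- args[1]
  fl <- .cli_flags(args[-1])
  out_dir <- fl$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- if (!is.null(fl$config)) read_config(fl$config) else default_config()
  for (k in intersect(names(fl), names(cfg))) cfg[[k]] <- fl[[k]]
  if (!is.null(fl$material)) cfg$material <- fl$material
  if (!is.null(fl$n)) cfg$n_particles <- as.integer(fl$n)
  if (!is.null(fl$duration)) cfg$duration_s <- fl$duration
  if (!is.null(fl$seed)) cfg$seed <- as.integer(fl$seed)
  env <- config_environment(cfg)
  rec <- config_recording(cfg)
  status <- 0L
  switch(sub,
    "simulate" = {
      pop <- sample_population(
        population_spec(cfg$material, cfg$n_particles,
                        config_size_model(cfg), env), seed = cfg$seed)
      sim <- simulate_population(pop, rec, env, seed = cfg$seed,
                                 init = cfg$init)
      tracks <- apply_localization_noise(sim$tracks, rec, seed = cfg$seed)
      write_tracks(tracks, file.path(out_dir, "tracks.csv"))
      write_truth(sim$truth, file.path(out_dir, "truth.csv"))
      message(sprintf("simulate: %d tracks -> %s", nrow(sim$truth), out_dir))
    },
    "detect" = {
      if (is.null(fl$volumes)) abort("detect needs --volumes <dir>.")
      vol <- read_volume_series(fl$volumes)
      px <- fl$px %||% (cfg$field_x_um / 2048)
      det <- detect_series(project_xyt(vol),
                           threshold = if (is.numeric(cfg$threshold))
                             cfg$threshold else "otsu",
                           px = c(px, px))
      readr::write_csv(det, file.path(out_dir, "detections.csv"))
      message(sprintf("detect: %d detections -> %s", nrow(det), out_dir))
    },
    "link" = {
      if (is.null(fl$detections)) abort("link needs --detections <csv>.")
      det <- readr::read_csv(fl$detections, col_types = readr::cols())
      trk <- link_detections(det, max_disp = fl$max_disp %||% cfg$max_disp_um,
                             gap_max = fl$gap_max %||% cfg$gap_max,
                             frame_rate = cfg$frame_rate)
      trk$z_um <- 0
      write_tracks(trk, file.path(out_dir, "tracks.csv"))
      message(sprintf("link: %d tracks -> %s",
                      dplyr::n_distinct(trk$track_id), out_dir))
    },
    "estimate" = {
      tracks <- read_tracks(fl$tracks %||% file.path(out_dir, "tracks.csv"))
      est <- estimate_particles(tracks, env, radius_source = cfg$radius_source,
                                fixed_radius_um = if (is.na(cfg$fixed_radius_um))
                                  NULL else cfg$fixed_radius_um,
                                dims = cfg$dims, max_lag = cfg$max_lag)
      est <- filter_outliers(est, "D_um2_s", cfg$outlier_D_cutoff_um2_s)
      write_estimates(est, file.path(out_dir, "estimates.csv"))
      message(sprintf("estimate: %d estimates -> %s", nrow(est), out_dir))
    },
    "classify" = {
      est <- read_estimates(fl$estimates %||% file.path(out_dir, "estimates.csv"))
      truth <- if (!is.null(fl$truth)) read_truth(fl$truth) else NULL
      cls <- classify_population(est, env$fluid,
                                 thresholds = c(cell = cfg$cell_threshold_kg_m3,
                                                mineral = cfg$mineral_threshold_kg_m3),
                                 truth = truth)
      write_classifications(cls, file.path(out_dir, "classifications.csv"))
      message(sprintf("classify: %d calls -> %s", nrow(cls), out_dir))
    },
    "plan" = {
      envs <- if (!is.null(fl$env)) fl$env else mission_environments()
      plan <- mission_plan(envs = envs, fluid = env$fluid,
                           duration_s = cfg$duration_s)
      write_classifications(plan, file.path(out_dir, "plan.csv"))
      message(sprintf("plan: %d rows -> %s", nrow(plan), out_dir))
    },
    "run-all" = {
      run_pipeline(cfg, out_dir = out_dir, seed = cfg$seed)
      message(sprintf("run-all: artifacts -> %s", out_dir))
    },
    abort(sprintf("Unknown subcommand '%s'.", sub))
  )
  invisible(status)
}
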