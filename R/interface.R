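#' Run configuration and pipeline entry points
#'
#' A run configuration (YAML or JSON) binds together input files, optimizer
#' settings and model switches. The `run_*()` functions are the programmatic
#' surface wrapped by the `dielcn` command-line script shipped in
#' `inst/scripts/`.
#'
#' @name interface
NULL

.default_config <- function() {
  list(
    condition = "Col-0_ambient",
    observations = NULL, gas_exchange = NULL, activities = NULL, bounds = NULL,
    output_dir = ".",
    rd = 5, gamma_star = 45, co2_ppm = 450, no3_total = 10, light_hours = 8,
    cv = 0.1, seed = 1,
    n_runs = 20, runs_per_step = 10, swarm_size = 24, iterations = 60,
    sd_band = 1, gate_carboxylates = TRUE, per_cytosol_volume = FALSE,
    rtol = 1e-6, atol = 1e-8
  )
}

#' Read and validate a run configuration
#'
#' Unknown keys are rejected; missing keys fall back to defaults. Referenced
#' input files must exist.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file, or a named list.
#' @return Validated configuration list (class `cn_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- .default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  # keep NULL-valued keys (unset file paths) instead of dropping them, so a
  # config round-trips losslessly
  for (k in names(cfg)) out[k] <- list(cfg[[k]])
  for (key in c("observations", "gas_exchange", "activities", "bounds")) {
    f <- out[[key]]
    if (!is.null(f) && !file.exists(f)) stop("config file missing on disk: ", f)
  }
  structure(out, class = "cn_config")
}

.config_control <- function(cfg) {
  pso_control(swarm_size = cfg$swarm_size, iterations = cfg$iterations,
              rtol = cfg$rtol, atol = cfg$atol)
}

.config_drivers <- function(cfg) {
  if (is.null(cfg$gas_exchange) || is.null(cfg$activities)) {
    stop("config must name gas_exchange and activities files")
  }
  gx <- read_gas_exchange(cfg$gas_exchange)
  act <- read_activities(cfg$activities)
  driver_set(
    ps = build_ps_spline(gx, rd = cfg$rd, light_hours = cfg$light_hours),
    rd = cfg$rd,
    vmax_nr = build_vmax_spline(act$NR, light_hours = cfg$light_hours),
    vmax_gs = build_vmax_spline(act$GS, light_hours = cfg$light_hours),
    vmax_hpr = build_vmax_spline(act$HPR, light_hours = cfg$light_hours),
    co2 = cfg$co2_ppm, gamma_star = cfg$gamma_star,
    no3_total = cfg$no3_total, light_hours = cfg$light_hours,
    per_cytosol_volume = cfg$per_cytosol_volume,
    gate_carboxylates = cfg$gate_carboxylates
  )
}

.config_bounds <- function(cfg) {
  if (is.null(cfg$bounds)) default_bounds() else read_bounds(cfg$bounds)
}

#' Generate the synthetic four-condition dataset
#'
#' @param config Path to a config file or a config list (see
#'   [read_run_config()]); uses `cv`, `seed` and `output_dir`.
#' @return The `cn_dataset`, invisibly; CSVs and a manifest are written to
#'   `output_dir`.
#' @export
run_synth <- function(config = list()) {
  cfg <- read_run_config(config)
  ds <- generate_dataset(cv = cfg$cv, seed = as.integer(cfg$seed),
                         dir = cfg$output_dir)
  message(sprintf("wrote %d condition dataset(s) to %s",
                  length(ds$conditions), cfg$output_dir))
  invisible(ds)
}

#' Fit an ensemble from configured inputs
#'
#' Writes `parameters.csv` (one row per run, with objective and acceptance)
#' and `mean_trajectory.csv` to `output_dir`.
#'
#' @inheritParams run_synth
#' @return The `cn_ensemble`, invisibly.
#' @export
run_fit <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$observations)) stop("config must name an observations file")
  obs <- read_observations(cfg$observations, condition = cfg$condition)
  drv <- .config_drivers(cfg)
  ens <- run_ensemble(obs, drv, .config_bounds(cfg), n_runs = cfg$n_runs,
                      base_seed = as.integer(cfg$seed),
                      control = .config_control(cfg), sd_band = cfg$sd_band)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  utils::write.csv(ensemble_parameters(ens),
                   file.path(cfg$output_dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(tidy_trajectory(ens$mean_trajectory, cfg$condition, 0L),
                   file.path(cfg$output_dir, "mean_trajectory.csv"), row.names = FALSE)
  message(sprintf("ensemble of %d: median error %.3f%%, %d accepted",
                  length(ens$fits), stats::median(ens$objectives),
                  ens$acceptance_count))
  invisible(ens)
}

#' Run the nocturnal GS-inactivation scan from configured inputs
#'
#' Writes `gs_scan.csv` (factor, run, error, accepted) to `output_dir`.
#'
#' @inheritParams run_synth
#' @return The `cn_gs_scan`, invisibly.
#' @export
run_gs_scan <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$observations)) stop("config must name an observations file")
  obs <- read_observations(cfg$observations, condition = cfg$condition)
  drv <- .config_drivers(cfg)
  scan <- gs_inactivation_scan(obs, drv, .config_bounds(cfg),
                               runs_per_step = cfg$runs_per_step,
                               base_seed = as.integer(cfg$seed),
                               control = .config_control(cfg),
                               sd_band = cfg$sd_band)
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  utils::write.csv(scan$results, file.path(cfg$output_dir, "gs_scan.csv"),
                   row.names = FALSE)
  message(sprintf("error-minimizing nocturnal GS factor: %.1f", scan$best_factor))
  invisible(scan)
}

#' Fit an ensemble and extract fluxes and light-phase flux ratios
#'
#' Writes `fluxes.csv` and `ratios.csv` to `output_dir`.
#'
#' @inheritParams run_synth
#' @return List with `ensemble`, `fluxes`, `ratios`, invisibly.
#' @export
run_fluxes <- function(config) {
  cfg <- read_run_config(config)
  ens <- run_fit(cfg)
  drv <- .config_drivers(cfg)
  fl <- extract_fluxes(ens, drv,
                       times = setdiff(ens$fits[[1]]$trajectory$time_h, 24))
  ra <- flux_ratios(fl, light_hours = cfg$light_hours)
  utils::write.csv(fl, file.path(cfg$output_dir, "fluxes.csv"), row.names = FALSE)
  utils::write.csv(ra, file.path(cfg$output_dir, "ratios.csv"), row.names = FALSE)
  message(sprintf("wrote %d flux rows, %d ratio rows (%d excluded)",
                  nrow(fl), nrow(ra), attr(ra, "n_excluded")))
  invisible(list(ensemble = ens, fluxes = fl, ratios = ra))
}
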