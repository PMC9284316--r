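#' Synthetic study-shaped data generation
#'
#' Emulates the measurement design of a diurnal C/N study on Arabidopsis
#' rosettes: four conditions (wildtype Col-0 and an hpr1-1-like HPR-deficient
#' mutant, each at ambient 450 ppm and elevated 1000 ppm CO2), an 8 h light /
#' 16 h dark cycle, metabolite harvests every 2 h at fivefold replication,
#' gas-exchange time series, and enzyme maximum activities (NR, GS, HPR) at
#' four diurnal time points. Ground-truth parameters are embedded so every
#' downstream stage (fitting, scans, flux extraction) can be tested for
#' recovery.
#'
#' @name synthetic_data
NULL

#' Default condition specifications
#'
#' Light-phase mean net photosynthesis per condition follows the measured
#' contrasts of the emulated study design (85.4 / 128.1 umol g-1 FW h-1 for
#' the wildtype at ambient/elevated CO2; 76.8 / 98.6 for the mutant). The
#' mutant differs from the wildtype ground truth solely by scaling the HPR
#' activity curve (default to 10 %), the lesion it models.
#'
#' @param params Wildtype ground-truth parameters (default
#'   [default_params()]).
#' @param hpr_scale HPR activity scale of the mutant (default 0.1).
#' @return Named list of four `cn_condition_spec` objects.
#' @export
default_condition_specs <- function(params = default_params(), hpr_scale = 0.1) {
  base <- list(
    rd = 5, gamma_star = 45, no3_total = 10,
    light_hours = 8,
    activities = list(
      NR = data.frame(time_h = c(0, 4, 8, 16), vmax = c(1.5, 1.8, 1.6, 1.0)),
      GS = data.frame(time_h = c(0, 4, 8, 16), vmax = c(34, 38, 36, 26)),
      HPR = data.frame(time_h = c(0, 4, 8, 16), vmax = c(14, 15, 14, 10))
    ),
    y0 = metabolite_state(
      gly = 0.3, ser = 1.0, hp = 0.8, mf = 12, cit = 10, kg = 0.3,
      glu = 8, gln = 2.5, aa = 18, nh4 = 0.4
    ),
    params = kinetic_params(values = unclass(params))
  )
  mean_ps <- c("Col-0_ambient" = 85.4, "Col-0_eCO2" = 128.1,
               "hpr1-1_ambient" = 76.8, "hpr1-1_eCO2" = 98.6)
  co2 <- c(450, 1000, 450, 1000)
  specs <- lapply(seq_along(mean_ps), function(i) {
    s <- base
    s$condition <- names(mean_ps)[i]
    s$genotype <- if (grepl("^Col-0", s$condition)) "Col-0" else "hpr1-1"
    s$co2_ppm <- co2[i]
    s$mean_ps <- unname(mean_ps[i])
    if (s$genotype == "hpr1-1") {
      s$activities$HPR$vmax <- s$activities$HPR$vmax * hpr_scale
    }
    structure(s, class = "cn_condition_spec")
  })
  stats::setNames(specs, names(mean_ps))
}

#' Generate a diurnal gas-exchange series for a condition
#'
#' A smooth light-phase arch (square-root-of-sine: fast post-dawn rise,
#' flat top) anchored at `-rd` at light-on and light-off, scaled so that the
#' light-phase mean equals the condition's mean net
#' photosynthesis; the dark phase sits at `-rd`. Sampled on a regular grid.
#'
#' @param spec A `cn_condition_spec`.
#' @param dt Sampling interval (h), default 0.5.
#' @return Data frame `time_h, flux` covering `[0, 24)`.
#' @export
synthetic_gas_exchange <- function(spec, dt = 0.5) {
  lh <- spec$light_hours
  tt <- seq(0, 24 - dt, by = dt)
  shape <- function(x) sqrt(sin(pi * x))        # fast rise, flat top
  norm <- mean(shape(seq(1e-6, 1 - 1e-6, length.out = 2001)))
  amp <- (spec$mean_ps + spec$rd) / norm
  flux <- ifelse(tt < lh, -spec$rd + amp * shape(pmin(tt / lh, 1)), -spec$rd)
  data.frame(time_h = tt, flux = flux)
}

#' Build the driver set implied by a condition specification
#'
#' @param spec A `cn_condition_spec`.
#' @param f_gs_night_sim Nocturnal GS factor applied inside the forward
#'   simulation (the reported activity series stays at the in vitro values);
#'   defaults to the spec's ground-truth `f_gs_night`.
#' @return A `cn_drivers` object built from the in vitro activity series.
#' @export
condition_drivers <- function(spec, f_gs_night_sim = NULL) {
  gx <- synthetic_gas_exchange(spec)
  driver_set(
    ps = build_ps_spline(gx, rd = spec$rd, light_hours = spec$light_hours),
    rd = spec$rd,
    vmax_nr = build_vmax_spline(spec$activities$NR, light_hours = spec$light_hours),
    vmax_gs = build_vmax_spline(spec$activities$GS, light_hours = spec$light_hours),
    vmax_hpr = build_vmax_spline(spec$activities$HPR, light_hours = spec$light_hours),
    co2 = spec$co2_ppm, gamma_star = spec$gamma_star,
    no3_total = spec$no3_total, light_hours = spec$light_hours
  )
}

#' Noise-free forward simulation of one condition
#'
#' Runs the model under the condition's ground-truth parameters (the
#' nocturnal GS down-regulation enters the simulation through `f_gs_night`,
#' while the activity series keeps the in vitro values a bench assay would
#' report).
#'
#' @param spec A `cn_condition_spec`.
#' @param t_grid Output grid (default 2-h harvest grid 0..22 plus 24).
#' @return List with `trajectory`, `drivers`, `gas_exchange`, `spec`.
#' @export
simulate_condition <- function(spec, t_grid = c(seq(0, 22, by = 2), 24)) {
  drv <- condition_drivers(spec)
  traj <- simulate_model(spec$params, drv, spec$y0, t_grid = t_grid)
  list(trajectory = traj, drivers = drv,
       gas_exchange = synthetic_gas_exchange(spec), spec = spec)
}

#' Draw replicate observations around a trajectory
#'
#' Multiplicative lognormal noise with coefficient of variation `cv`
#' (metabolite-assay-like heteroscedasticity), mean-one scaling; `n` draws per
#' state and harvest time.
#'
#' @param trajectory A `cn_trajectory`.
#' @param n Replicates per cell (default 5).
#' @param cv Coefficient of variation (default 0.1).
#' @param seed Integer seed (draws are reproducible for a fixed seed).
#' @param times Harvest times (default: every 2 h, 0..22).
#' @return Data frame `state, time_h, mean, sd, n` plus a `replicates`
#'   attribute (long data frame of individual draws).
#' @export
sample_replicates <- function(trajectory, n = 5, cv = 0.1, seed = 1L,
                              times = seq(0, 22, by = 2)) {
  if (cv < 0) stop("cv must be >= 0")
  if (!all(times %in% trajectory$time_h)) stop("times must be on the trajectory grid")
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2
  rows <- match(times, trajectory$time_h)
  grid <- expand.grid(state = state_names(), time_h = times,
                      stringsAsFactors = FALSE)
  out <- local_seed(seed, {
    reps <- lapply(seq_len(nrow(grid)), function(i) {
      truth <- trajectory[rows[match(grid$time_h[i], times)], grid$state[i]]
      if (cv == 0) rep(truth, n) else truth * stats::rlnorm(n, mulog, sdlog)
    })
    reps
  })
  grid$mean <- vapply(out, mean, 0)
  grid$sd <- vapply(out, stats::sd, 0)
  grid$n <- n
  reps_long <- data.frame(
    state = rep(grid$state, each = n),
    time_h = rep(grid$time_h, each = n),
    replicate = rep(seq_len(n), times = nrow(grid)),
    value = unlist(out, use.names = FALSE)
  )
  attr(grid, "replicates") <- reps_long
  grid
}

#' Generate the full four-condition synthetic dataset
#'
#' @param specs Condition specifications (default
#'   [default_condition_specs()]).
#' @param cv Replicate coefficient of variation (default 0.1).
#' @param seed Integer seed; per-condition seeds are derived from it.
#' @param dir Optional output directory; when given, per-condition CSVs
#'   (`<condition>_observations.csv`, `<condition>_gas_exchange.csv`,
#'   `<condition>_activities.csv`) and a `manifest.json` are written.
#' @return Object of class `cn_dataset`: per-condition observations,
#'   gas-exchange and activity tables, trajectories, ground truth and seed.
#' @export
generate_dataset <- function(specs = default_condition_specs(), cv = 0.1,
                             seed = 1L, dir = NULL) {
  if (!length(specs)) stop("specs must be non-empty")
  conditions <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    sim <- simulate_condition(spec)
    obs <- sample_replicates(sim$trajectory, n = 5, cv = cv,
                             seed = derive_seed(seed, i))
    act <- do.call(rbind, lapply(names(spec$activities), function(e) {
      data.frame(enzyme = e, spec$activities[[e]])
    }))
    list(condition = spec$condition, observations = obs,
         gas_exchange = sim$gas_exchange, activities = act,
         trajectory = sim$trajectory, spec = spec)
  })
  names(conditions) <- names(specs)
  ds <- structure(list(conditions = conditions, cv = cv, seed = seed),
                  class = "cn_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @rdname generate_dataset
#' @param ds A `cn_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cond in ds$conditions) {
    stub <- file.path(dir, gsub("[^A-Za-z0-9_.-]", "_", cond$condition))
    obs <- cond$observations
    obs <- data.frame(condition = cond$condition,
                      obs[c("state", "time_h", "mean", "sd", "n")])
    utils::write.csv(obs, paste0(stub, "_observations.csv"), row.names = FALSE)
    utils::write.csv(cond$gas_exchange, paste0(stub, "_gas_exchange.csv"),
                     row.names = FALSE)
    utils::write.csv(cond$activities, paste0(stub, "_activities.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = ds$seed, cv = ds$cv,
    conditions = lapply(ds$conditions, function(cond) {
      s <- cond$spec
      list(condition = s$condition, genotype = s$genotype,
           co2_ppm = s$co2_ppm, mean_ps = s$mean_ps, rd = s$rd,
           gamma_star = s$gamma_star, no3_total = s$no3_total,
           light_hours = s$light_hours,
           y0 = as.list(unclass(s$y0)),
           ground_truth = as.list(unclass(s$params)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.cn_dataset <- function(x, ...) {
  cat("<cn_dataset>", length(x$conditions), "condition(s), cv =", x$cv,
      ", seed =", x$seed, "\n")
  for (cond in x$conditions) {
    cat(sprintf("  %-16s %4d observation cells\n", cond$condition,
                nrow(cond$observations)))
  }
  invisible(x)
}
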