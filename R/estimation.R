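#' Parameter identification against diurnal metabolite time courses
#'
#' Parameters are identified by minimizing the averaged relative deviation
#' between simulated and measured pool contents over all states and harvest
#' time points, using a particle-swarm optimizer within box bounds. Fits are
#' run as ensembles of independently seeded optimizations; a fit is accepted
#' when every simulated state lies within the measured standard deviation at
#' every time point.
#'
#' @name estimation
NULL

#' Averaged percent error of a trajectory against observations
#'
#' `100 * mean(|sim - mean| / max(mean, eps))` over every (state, time)
#' observation cell; `eps` (default 1e-3 umol g-1 FW) floors the denominator
#' so near-zero means do not dominate.
#'
#' @param trajectory A `cn_trajectory` sampled at (at least) the observation
#'   times.
#' @param observations Data frame with columns `state`, `time_h`, `mean`
#'   (and optionally `sd`, `n`).
#' @param eps Denominator floor (umol g-1 FW).
#' @return Non-negative scalar, in percent per state and time point.
#' @export
objective_error <- function(trajectory, observations, eps = 1e-3) {
  need <- c("state", "time_h", "mean")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns: ", paste(need, collapse = ", "))
  }
  rows <- match(observations$time_h, trajectory$time_h)
  if (any(is.na(rows))) stop("validation error: observation times missing from trajectory")
  bad <- !observations$state %in% setdiff(names(trajectory), "time_h")
  if (any(bad)) {
    stop("validation error: unknown state(s): ",
         paste(unique(observations$state[bad]), collapse = ", "))
  }
  sim <- vapply(seq_len(nrow(observations)), function(i) {
    trajectory[[observations$state[i]]][rows[i]]
  }, 0)
  100 * mean(abs(sim - observations$mean) / pmax(observations$mean, eps))
}

#' Particle-swarm optimizer settings
#'
#' Desk-scale defaults: 24 particles, 60 iterations, constriction-type
#' coefficients (inertia 0.7298, cognitive/social 1.49618), velocities
#' clamped to half the box width.
#'
#' @param swarm_size Number of particles.
#' @param iterations Number of update sweeps.
#' @param inertia,c_cog,c_soc PSO coefficients.
#' @param vmax_frac Velocity clamp as a fraction of each box width.
#' @param rtol,atol Integration tolerances used inside the objective.
#' @param penalty Objective value assigned to failed integrations.
#' @return List of settings.
#' @export
pso_control <- function(swarm_size = 24, iterations = 60, inertia = 0.7298,
                        c_cog = 1.49618, c_soc = 1.49618, vmax_frac = 0.5,
                        rtol = 1e-6, atol = 1e-8, penalty = 1e6) {
  list(swarm_size = swarm_size, iterations = iterations, inertia = inertia,
       c_cog = c_cog, c_soc = c_soc, vmax_frac = vmax_frac,
       rtol = rtol, atol = atol, penalty = penalty)
}

# Global-best PSO over a box; deterministic given the enclosing RNG state.
.pso_minimize <- function(fn, lower, upper, control) {
  d <- length(lower)
  ns <- control$swarm_size
  span <- upper - lower
  vmax <- control$vmax_frac * span
  # stratified (Latin-hypercube) initial positions: one particle per stratum
  # in every dimension, jittered within the stratum
  u <- vapply(seq_len(d), function(j) {
    (sample.int(ns) - stats::runif(ns)) / ns
  }, numeric(ns))
  x <- sweep(sweep(u, 2, span, "*"), 2, lower, "+")
  v <- matrix(stats::runif(ns * d, -vmax, vmax), nrow = ns, byrow = TRUE)
  f <- apply(x, 1, fn)
  pbest_x <- x; pbest_f <- f
  g <- which.min(f)
  gbest_x <- x[g, ]; gbest_f <- f[g]
  n_eval <- ns
  for (it in seq_len(control$iterations)) {
    r1 <- matrix(stats::runif(ns * d), nrow = ns)
    r2 <- matrix(stats::runif(ns * d), nrow = ns)
    v <- control$inertia * v +
      control$c_cog * r1 * (pbest_x - x) +
      control$c_soc * r2 * sweep(x, 2, gbest_x, "-") * -1
    v <- pmin(pmax(v, matrix(-vmax, ns, d, byrow = TRUE)),
              matrix(vmax, ns, d, byrow = TRUE))
    x <- x + v
    # reflect at the box and zero the offending velocity component
    lo <- matrix(lower, ns, d, byrow = TRUE)
    hi <- matrix(upper, ns, d, byrow = TRUE)
    out_lo <- x < lo; out_hi <- x > hi
    x[out_lo] <- lo[out_lo]; x[out_hi] <- hi[out_hi]
    v[out_lo | out_hi] <- 0
    f <- apply(x, 1, fn)
    n_eval <- n_eval + ns
    better <- f < pbest_f
    pbest_x[better, ] <- x[better, , drop = FALSE]
    pbest_f[better] <- f[better]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest_f <- pbest_f[g]
      gbest_x <- pbest_x[g, ]
    }
  }
  list(par = gbest_x, value = gbest_f, n_eval = n_eval)
}

.initial_state_from_obs <- function(observations) {
  at0 <- observations[observations$time_h == min(observations$time_h), ]
  y0 <- stats::setNames(at0$mean, at0$state)
  miss <- setdiff(state_names(), names(y0))
  if (length(miss)) stop("observations lack t = 0 values for: ", paste(miss, collapse = ", "))
  metabolite_state(pmax(y0[state_names()], 0))
}

#' Fit kinetic parameters to observations
#'
#' Minimizes [objective_error()] over the box given by `bounds` with a
#' particle swarm. The initial state is taken from the observation means at
#' the first harvest time (the start of the light phase); only those means
#' are used as initial values, the remaining time points constrain the fit.
#' Integration failures inside the search are penalized, not fatal.
#'
#' @param observations Data frame `state, time_h, mean, sd, n`.
#' @param drivers A `cn_drivers` object.
#' @param bounds Data frame `parameter, lower, upper` covering all model
#'   parameters; a parameter with `lower == upper` is fixed at that value.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param fixed Optional named numeric vector of parameters to fix (removed
#'   from the search; e.g. `c(f_gs_night = 0.3)` for the nocturnal GS scan).
#' @param control Optimizer settings from [pso_control()].
#' @param sd_band Acceptance band width in standard deviations (default 1).
#' @return Object of class `cn_fit`: `params`, `objective` (percent),
#'   `accepted`, `seed`, `trajectory`, `n_failed` integrations.
#' @export
fit_parameters <- function(observations, drivers, bounds = default_bounds(),
                           seed = 1L, fixed = NULL, control = pso_control(),
                           sd_band = 1) {
  validate_bounds(bounds)
  b <- bounds[match(param_names(), bounds$parameter), ]
  lower <- stats::setNames(b$lower, b$parameter)
  upper <- stats::setNames(b$upper, b$parameter)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), param_names())
    if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
    lower[names(fixed)] <- fixed
    upper[names(fixed)] <- fixed
  }
  free <- names(lower)[upper > lower]
  template <- stats::setNames((lower + upper) / 2, names(lower))

  y0 <- .initial_state_from_obs(observations)
  times <- sort(unique(observations$time_h))
  if (times[1] != 0) times <- c(0, times)
  n_failed <- 0L

  make_params <- function(x) {
    template[free] <- x
    structure(template, class = "cn_params")
  }
  fn <- function(x) {
    p <- make_params(x)
    tr <- tryCatch(
      suppressWarnings(simulate_model(p, drivers, y0, t_grid = times,
                                      rtol = control$rtol, atol = control$atol)),
      error = function(e) NULL
    )
    if (is.null(tr)) {
      n_failed <<- n_failed + 1L
      return(control$penalty)
    }
    objective_error(tr, observations)
  }

  res <- if (length(free)) {
    local_seed(seed, .pso_minimize(fn, lower[free], upper[free], control))
  } else {
    list(par = numeric(0), value = fn(numeric(0)), n_eval = 1L)
  }
  if (res$value >= control$penalty) {
    stop("optimization error: every candidate parameterization failed to integrate")
  }
  params <- make_params(res$par)
  traj <- suppressWarnings(simulate_model(params, drivers, y0, t_grid = times,
                                          rtol = control$rtol, atol = control$atol))
  rows <- match(observations$time_h, traj$time_h)
  sim <- vapply(seq_len(nrow(observations)), function(i) {
    traj[[observations$state[i]]][rows[i]]
  }, 0)
  accepted <- if ("sd" %in% names(observations)) {
    all(abs(sim - observations$mean) <= sd_band * observations$sd)
  } else NA
  structure(list(params = params, objective = res$value, accepted = accepted,
                 seed = seed, trajectory = traj, n_eval = res$n_eval,
                 n_failed = n_failed, free = free),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("<cn_fit> objective %.4f%%, accepted: %s, seed %d (%d evals, %d failed)\n",
              x$objective, as.character(x$accepted), x$seed, x$n_eval, x$n_failed))
  invisible(x)
}

#' Run an ensemble of independently seeded fits
#'
#' @inheritParams fit_parameters
#' @param n_runs Number of ensemble members (study-scale default 20).
#' @param base_seed Base seed; member seeds are derived as
#'   `derive_seed(base_seed, run)`.
#' @return Object of class `cn_ensemble`: `fits`, per-state `mean_trajectory`
#'   (arithmetic mean over members), `acceptance_count`, `objectives`.
#' @export
run_ensemble <- function(observations, drivers, bounds = default_bounds(),
                         n_runs = 20, base_seed = 1L, fixed = NULL,
                         control = pso_control(), sd_band = 1) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  fits <- lapply(seq_len(n_runs), function(i) {
    fit_parameters(observations, drivers, bounds,
                   seed = derive_seed(base_seed, i), fixed = fixed,
                   control = control, sd_band = sd_band)
  })
  tmat <- Reduce(`+`, lapply(fits, function(f) as.matrix(f$trajectory[, -1]))) / n_runs
  mean_traj <- data.frame(time_h = fits[[1]]$trajectory$time_h, tmat)
  names(mean_traj) <- c("time_h", state_names())
  class(mean_traj) <- c("cn_trajectory", "data.frame")
  structure(list(
    fits = fits,
    mean_trajectory = mean_traj,
    objectives = vapply(fits, function(f) f$objective, 0),
    acceptance_count = sum(vapply(fits, function(f) isTRUE(f$accepted), NA)),
    base_seed = base_seed
  ), class = "cn_ensemble")
}

#' @export
print.cn_ensemble <- function(x, ...) {
  cat(sprintf("<cn_ensemble> %d fit(s); objective median %.4f%% (best %.4f%%); %d accepted\n",
              length(x$fits), stats::median(x$objectives), min(x$objectives),
              x$acceptance_count))
  invisible(x)
}

#' Parameter table of an ensemble
#'
#' @param ensemble A `cn_ensemble`.
#' @return Data frame: one row per run, columns `run`, `seed`, `objective`,
#'   `accepted`, then every parameter.
#' @export
ensemble_parameters <- function(ensemble) {
  do.call(rbind, lapply(seq_along(ensemble$fits), function(i) {
    f <- ensemble$fits[[i]]
    cbind(data.frame(run = i, seed = f$seed, objective = f$objective,
                     accepted = f$accepted),
          as.data.frame(as.list(unclass(f$params))))
  }))
}

#' Lower Km bound for the HPR reaction in the mutant
#'
#' The minimum HPR Km identified across a wildtype ensemble is used as the
#' lower search bound when fitting the HPR-deficient mutant, so a low vmax
#' cannot be compensated by an arbitrarily low Km. Optionally the bound is
#' relaxed by a further 30 % reduction.
#'
#' @param col0_ensemble Wildtype `cn_ensemble`.
#' @param relax Allow the additional 30 % reduction (default FALSE).
#' @return Scalar lower bound for `km_hpr` (mM).
#' @export
hpr_km_bound <- function(col0_ensemble, relax = FALSE) {
  if (!length(col0_ensemble$fits)) stop("validation error: empty ensemble")
  kms <- vapply(col0_ensemble$fits, function(f) unclass(f$params)[["km_hpr"]], 0)
  b <- min(kms)
  if (relax) b <- 0.7 * b
  b
}

#' Read an observations CSV
#'
#' Expects columns `state, time_h, mean, sd, n` (an optional `condition`
#' column is preserved).
#'
#' @param path CSV file path.
#' @param condition Optional condition label to filter on.
#' @return Data frame of observations.
#' @export
read_observations <- function(path, condition = NULL) {
  d <- utils::read.csv(path)
  need <- c("state", "time_h", "mean", "sd", "n")
  if (!all(need %in% names(d))) {
    stop("observations file must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(condition) && "condition" %in% names(d)) {
    d <- d[d$condition == condition, , drop = FALSE]
  }
  if (any(d$sd < 0)) stop("validation error: negative sd")
  d
}

#' Read a parameter-bounds CSV (columns `parameter, lower, upper`)
#'
#' @param path CSV file path.
#' @return Validated bounds data frame.
#' @export
read_bounds <- function(path) {
  validate_bounds(utils::read.csv(path))
}
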