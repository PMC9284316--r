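#' The diurnal C/N network model
#'
#' Ten dynamic pools (umol g-1 FW) inside the system boundary: glycine (gly),
#' serine (ser), hexose phosphates in C6 equivalents (hp), malate + fumarate
#' (mf), citrate (cit), alpha-ketoglutarate (kg), glutamate (glu), glutamine
#' (gln), the free amino-acid pool excluding Gly/Ser/Glu/Gln (aa), and
#' ammonium (nh4). O2, CO2, biomass, starch, exported assimilate and nitrate
#' are outside the boundary: their exchange rates appear as fluxes but their
#' amounts are not tracked.
#'
#' @name model
NULL

state_names <- function() {
  c("gly", "ser", "hp", "mf", "cit", "kg", "glu", "gln", "aa", "nh4")
}

flux_names <- function() {
  c("v_ps_in", "v_starch", "v_pr", "v_gdc", "v_shmt", "v_hpr",
    "v_ser2aa", "v_ser2bm", "v_glu2kg", "v_gs", "v_gogat", "v_nr",
    "v_glu2aa", "v_aa2bmexp", "v_hp2bmexp", "v_hp2mf",
    "v_mf2cit", "v_cit2mf", "v_cit2kg", "v_resp")
}

#' Construct and validate a metabolite state
#'
#' @param ... Named pool contents (umol g-1 FW) or a single named vector.
#' @return Named numeric vector of the 10 pools, class `cn_state`.
#' @export
metabolite_state <- function(...) {
  x <- c(...)
  miss <- setdiff(state_names(), names(x))
  if (length(miss)) stop("missing state(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(x), state_names())
  if (length(extra)) stop("unknown state(s): ", paste(extra, collapse = ", "))
  x <- x[state_names()]
  if (any(!is.finite(x)) || any(x < 0)) stop("pool contents must be finite and >= 0")
  structure(x, class = "cn_state")
}

# Smooth depletion gate for fluxes whose rate law does not contain the donor
# pool: ~1 at healthy pool sizes, -> 0 as the pool empties. The width (1e-4
# umol/gFW) trades exactness of the derived-flux identities (deviation
# <= gate_eps/pool, i.e. ~0.01% at pools of order 1) for integrator stability
# at sharp depletions.
.gate_eps <- 1e-4
.gate <- function(s) {
  s <- pmax(s, 0)
  s / (s + .gate_eps)
}

# Core flux computation, unnamed numeric in flux_names() order.
# `y` may be un-validated (integrator states); negatives are treated as 0.
.flux_core <- function(t, y, p, d) {
  tm <- t %% 24
  light <- tm < d$light_hours

  gly <- max(y[1L], 0); ser <- max(y[2L], 0); hp <- max(y[3L], 0)
  mf <- max(y[4L], 0); cit <- max(y[5L], 0); kg <- max(y[6L], 0)
  glu <- max(y[7L], 0); gln <- max(y[8L], 0); aa <- max(y[9L], 0)
  nh4 <- max(y[10L], 0)
  vol <- .tissue_volume_ml_per_g

  a_net <- d$ps(t)
  v_o <- if (light) max((a_net + d$rd) / (1 / d$phi - 0.5), 0) else 0
  v_pr <- if (light) v_o / 2 + p[["alpha"]] else p[["alpha"]]

  gly_c <- gly / vol
  v_gdc <- p[["vmax_gdc"]] * gly_c / (p[["km_gdc"]] + gly_c)
  v_shmt <- min(p[["vmax_shmt"]] * gly_c / (p[["km_shmt"]] + gly_c), v_gdc)

  ser_c <- ser / vol
  v_hpr <- d$vmax_hpr(t) * ser_c / (p[["km_hpr"]] + ser_c)

  v_nr <- d$vmax_nr(t) * d$no3_cyt / (p[["km_nr"]] + d$no3_cyt)

  nh4_c <- nh4 / vol; glu_c <- glu / vol
  vgs <- d$vmax_gs(t) * (if (light) 1 else p[["f_gs_night"]])
  v_gs <- vgs * nh4_c / (p[["km_gs_nh4"]] + nh4_c) *
    glu_c / (p[["km_gs_glu"]] + glu_c)

  gln_c <- gln / vol; kg_c <- kg / vol
  v_gogat <- p[["vmax_gogat"]] * gln_c / (p[["km_gogat_gln"]] + gln_c) *
    kg_c / (p[["km_gogat_kg"]] + kg_c)

  v_hp2bmexp <- p[["k_hp2bmexp"]] * hp
  v_hp2mf <- p[["k_hp2mf"]] * hp
  gate_cx <- d$gate_carboxylates
  v_mf2cit <- p[["k_mf2cit"]] * mf * (if (gate_cx && light) 0 else 1)
  v_cit2mf <- p[["k_cit2mf"]] * cit
  v_cit2kg <- p[["k_cit2kg"]] * cit * (if (gate_cx && !light) 0 else 1)
  v_ser2aa <- p[["k_ser2aa"]] * ser
  v_aa2bmexp <- p[["k_aa2bmexp"]] * aa
  v_ser2bm <- 0.14 * v_aa2bmexp * .gate(ser)
  v_glu2kg <- max(v_pr - v_hpr, 0) * .gate(glu)
  v_glu2aa <- p[["correct"]] * v_nr * .gate(glu)
  v_resp <- d$rd / 4 * .gate(mf)
  v_starch <- if (light) p[["s_day"]] * .gate(hp) else
    p[["s_day"]] * d$light_hours / (24 - d$light_hours)

  v_ps_in <- (a_net + d$rd + v_gdc - 2 * v_pr) / 6

  c(v_ps_in, v_starch, v_pr, v_gdc, v_shmt, v_hpr,
    v_ser2aa, v_ser2bm, v_glu2kg, v_gs, v_gogat, v_nr,
    v_glu2aa, v_aa2bmexp, v_hp2bmexp, v_hp2mf,
    v_mf2cit, v_cit2mf, v_cit2kg, v_resp)
}

# Derivative assembly from a flux vector in flux_names() order.
.deriv_core <- function(v, light) {
  starch_hp <- if (light) -v[2L] else v[2L]
  c(
    v[3L] - v[4L] - v[5L],                              # gly
    v[5L] - v[6L] - v[7L] - v[8L],                      # ser
    v[1L] + 0.5 * v[6L] - v[15L] - v[16L] + starch_hp,  # hp
    1.5 * v[16L] + 1.5 * v[18L] - 1.5 * v[17L] - v[20L],# mf
    v[17L] - v[18L] - v[19L],                           # cit
    1.2 * v[19L] + v[9L] - v[11L],                      # kg
    2 * v[11L] - v[10L] - v[9L] - v[13L],               # glu
    v[10L] - v[11L],                                    # gln
    v[7L] + v[13L] - v[14L],                            # aa
    v[4L] + v[12L] - v[10L]                             # nh4
  )
}

#' Evaluate every reaction flux at a state and time
#'
#' Applies the rate-law table of the network: first-order mass-balance
#' kinetics for the carbon export, carboxylate and amino-acid turnover steps;
#' Michaelis-Menten kinetics for GDC, SHMT (capped by GDC), HPR, NR
#' (on the cytosolic nitrate fraction), GS (two-substrate in NH4+ and Glu,
#' vmax down-scaled by `f_gs_night` in the dark) and GOGAT (two-substrate in
#' Gln and alpha-KG); and the derived fluxes
#' `v_glu2kg = max(v_pr - v_hpr, 0)`, `v_glu2aa = correct * v_nr`,
#' `v_ser2bm = 0.14 * v_aa2bmexp`. Concentrations for Michaelis-Menten terms
#' use the 0.77 ml g-1 FW tissue-volume conversion.
#'
#' @param state Named pool vector (see [metabolite_state()]).
#' @param t Time of day (h).
#' @param params A `cn_params` vector.
#' @param drivers A `cn_drivers` object.
#' @return Named numeric vector of fluxes (umol g-1 FW h-1).
#' @export
evaluate_fluxes <- function(state, t, params, drivers) {
  validate_params(params)
  y <- unclass(state)[state_names()]
  if (any(is.na(y))) stop("state must contain all pools: ", paste(state_names(), collapse = ", "))
  v <- .flux_core(t, as.numeric(y), unclass(params), drivers)
  stats::setNames(v, flux_names())
}

#' Time derivative of the metabolite state
#'
#' Assembles d(state)/dt from the flux vector with the stoichiometric
#' conversion factors of the network (pools in umol of metabolite; HP in
#' hexose equivalents, so e.g. one HPR unit returns 0.5 HP and one HP makes
#' 1.5 malate+fumarate units).
#'
#' @inheritParams evaluate_fluxes
#' @return Named numeric vector of derivatives (umol g-1 FW h-1).
#' @export
model_rhs <- function(state, t, params, drivers) {
  v <- evaluate_fluxes(state, t, params, drivers)
  d <- .deriv_core(as.numeric(v), is_light(t, drivers$light_hours))
  if (any(!is.finite(d))) {
    stop(sprintf("non-finite derivative at t = %.4f h (state: %s)",
                 t, paste(sprintf("%.3g", state), collapse = ", ")))
  }
  stats::setNames(d, state_names())
}

# Sample the four driver curves onto the uniform grid the compiled model
# interpolates (t = 0, 0.01, ..., 24 h); cached per driver set.
.driver_grid_dt <- 0.01
.driver_tables <- function(drivers) {
  cache <- drivers$cache
  if (!is.null(cache) && !is.null(cache$tables)) return(cache$tables)
  lh <- drivers$light_hours
  tt <- seq(0, 24, by = .driver_grid_dt)
  te <- pmin(tt, 24 - 1e-12)   # keep t = 24 on the night side of the splines
  tabs <- c(ifelse(tt < lh, drivers$ps(tt), -drivers$rd),
            drivers$vmax_nr(te), drivers$vmax_gs(te), drivers$vmax_hpr(te))
  if (!is.null(cache)) cache$tables <- tabs
  tabs
}

.parms_vector <- function(p, drivers) {
  c(as.numeric(p[param_names()]), drivers$phi, drivers$rd, drivers$no3_cyt,
    drivers$light_hours, as.numeric(drivers$gate_carboxylates),
    .gate_eps, .tissue_volume_ml_per_g, .driver_tables(drivers))
}

#' Simulate the diurnal time course
#'
#' Integrates the ODE system with an adaptive stiff-capable method
#' (`deSolve::lsoda`), restarting the integration at the light/dark
#' transition so the driver discontinuity is never stepped over. The default
#' engine is the compiled right-hand side (driver splines sampled onto a
#' dense 0.02-h grid as linearly interpolated forcings); `engine = "R"` uses
#' the interpreted rate laws and exact spline evaluation. States that dip
#' below zero by more than ~100*atol are clipped with a warning; persistent
#' or macroscopic excursions fail the run.
#'
#' @param params A `cn_params` vector.
#' @param drivers A `cn_drivers` object.
#' @param y0 Initial state at t = 0 (start of the light phase).
#' @param t_grid Ascending output times in `[0, 24]`, starting at 0.
#' @param rtol,atol Integration tolerances.
#' @param engine `"compiled"` (default) or `"R"`.
#' @return Data frame (class `cn_trajectory`): column `time_h` plus one
#'   column per pool.
#' @export
simulate_model <- function(params, drivers, y0, t_grid = seq(0, 24, by = 0.25),
                           rtol = 1e-6, atol = 1e-10,
                           engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  validate_params(params)
  y <- as.numeric(unclass(y0)[state_names()])
  if (any(is.na(y)) || any(y < 0)) stop("y0 must contain all pools, >= 0")
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0 || max(t_grid) > 24) {
    stop("t_grid must be strictly ascending within [0, 24], starting at 0")
  }
  p <- unclass(params)
  lh <- drivers$light_hours
  t_end <- max(t_grid)
  cuts <- sort(unique(c(0, if (lh > 0 && lh < t_end) lh, t_end)))

  run_segment <- if (engine == "compiled") {
    pv <- .parms_vector(p, drivers)
    function(y0s, times) {
      deSolve::lsoda(y0s, times, func = "cn_derivs", parms = pv,
                     dllname = "dielCN", initfunc = "cn_initmod",
                     tcrit = max(times), rtol = rtol, atol = atol)
    }
  } else {
    func <- function(t, yy, parms) {
      # clamp so the final instant t = 24 stays on the night side, matching
      # the compiled engine (t %% 24 would wrap it to dawn)
      tc <- min(t, 24 - 1e-12)
      v <- .flux_core(tc, yy, p, drivers)
      list(.deriv_core(v, (tc %% 24) < lh))
    }
    function(y0s, times) {
      deSolve::lsoda(y0s, times, func, parms = NULL, rtol = rtol, atol = atol)
    }
  }

  rows <- list()
  ycur <- y
  for (k in seq_len(length(cuts) - 1)) {
    times <- sort(unique(c(cuts[k], t_grid[t_grid >= cuts[k] & t_grid <= cuts[k + 1]],
                           cuts[k + 1])))
    seg <- tryCatch(
      run_segment(ycur, times),
      warning = function(w) stop("integration failure: ", conditionMessage(w)),
      error = function(e) stop("integration failure: ", conditionMessage(e))
    )
    if (nrow(seg) < length(times)) {
      stop(sprintf("integration failure: stopped at t = %.4f h", seg[nrow(seg), 1]))
    }
    ycur <- as.numeric(seg[nrow(seg), -1])
    rows[[k]] <- seg
  }
  out <- do.call(rbind, rows)
  m <- out[match(t_grid, out[, 1]), -1, drop = FALSE]
  # Negatives are integrator overshoot at sharp pool depletions (the rate laws
  # make every derivative >= 0 at an empty pool). Jitter within 1e-6 umol/gFW
  # of zero -- far below anything measurable -- is zeroed silently; larger
  # excursions are clipped with a warning and fail the run when persistent
  # (> 0.1 % of values) or macroscopic (beyond 1e-4).
  neg <- m < -1e-6
  if (any(neg)) {
    if (any(m[neg] < -1e-4)) {
      stop(sprintf("integration failure: state fell to %.3g", min(m)))
    }
    if (mean(neg) > 1e-3) {
      stop(sprintf("integration failure: %.2f%% of reported values clipped below 0",
                   100 * mean(neg)))
    }
    warning(sprintf("clipped %d negative value(s) to 0 (min %.3g)",
                    sum(neg), min(m)))
  }
  m[m < 0] <- 0
  traj <- data.frame(time_h = t_grid, m)
  names(traj) <- c("time_h", state_names())
  class(traj) <- c("cn_trajectory", "data.frame")
  traj
}

#' Evaluate fluxes along a trajectory
#'
#' @param trajectory A `cn_trajectory` from [simulate_model()].
#' @param params,drivers Model inputs used for the simulation.
#' @param times Subset of trajectory times (default: all).
#' @return Data frame with `time_h` plus one column per flux.
#' @export
trajectory_fluxes <- function(trajectory, params, drivers, times = NULL) {
  if (is.null(times)) times <- trajectory$time_h
  if (!all(times %in% trajectory$time_h)) stop("times must be on the trajectory grid")
  rows <- match(times, trajectory$time_h)
  p <- unclass(params)
  v <- t(vapply(rows, function(i) {
    .flux_core(trajectory$time_h[i], as.numeric(trajectory[i, state_names()]), p, drivers)
  }, numeric(length(flux_names()))))
  out <- data.frame(time_h = times, v)
  names(out) <- c("time_h", flux_names())
  out
}

#' Tidy long-form exports
#'
#' `tidy_trajectory()` returns columns `condition, run_id, time_h, state,
#' value_umol_per_gFW`; `tidy_fluxes()` returns `condition, run_id, time_h,
#' flux, value_umol_per_gFW_per_h`.
#'
#' @param x Wide trajectory or flux table.
#' @param condition,run_id Identifier columns to attach.
#' @return Long-form data frame.
#' @export
tidy_trajectory <- function(x, condition = "unknown", run_id = 1L) {
  vars <- setdiff(names(x), "time_h")
  out <- data.frame(
    condition = condition, run_id = run_id,
    time_h = rep(x$time_h, times = length(vars)),
    state = rep(vars, each = nrow(x)),
    value_umol_per_gFW = unlist(x[vars], use.names = FALSE)
  )
  out[order(out$time_h, out$state), , drop = FALSE]
}

#' @rdname tidy_trajectory
#' @export
tidy_fluxes <- function(x, condition = "unknown", run_id = 1L) {
  vars <- setdiff(names(x), "time_h")
  out <- data.frame(
    condition = condition, run_id = run_id,
    time_h = rep(x$time_h, times = length(vars)),
    flux = rep(vars, each = nrow(x)),
    value_umol_per_gFW_per_h = unlist(x[vars], use.names = FALSE)
  )
  out[order(out$time_h, out$flux), , drop = FALSE]
}
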