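#' Numerical experiments on fitted ensembles
#'
#' The nocturnal GS-inactivation scan, flux time-course extraction and the
#' NR/GDC and HP2BMEXP/NR flux-ratio analyses.
#'
#' @name experiments
NULL

#' Nocturnal GS inactivation scan
#'
#' Fixes the nocturnal GS factor to each value of a descending 10 %-step grid
#' (1.0 down to 0.1), re-optimizes all remaining parameters several times per
#' step, and reports the factor minimizing the median objective error.
#'
#' @inheritParams fit_parameters
#' @param runs_per_step Independent fits per factor (study-scale default 10).
#' @param factors Scan grid (default `seq(1, 0.1, by = -0.1)`).
#' @param base_seed Base seed; each (factor, run) pair gets a derived seed.
#' @return Object of class `cn_gs_scan`: `results` (factor, run, seed, error,
#'   accepted), `summary` (factor, median_error, acceptance), `best_factor`.
#' @export
gs_inactivation_scan <- function(observations, drivers, bounds = default_bounds(),
                                 runs_per_step = 10,
                                 factors = seq(1, 0.1, by = -0.1),
                                 base_seed = 1L, control = pso_control(),
                                 sd_band = 1) {
  if (any(factors <= 0 | factors > 1)) stop("factors must lie in (0, 1]")
  factors <- round(factors, 9)   # normalize seq() float jitter (0.4000000000000001)
  rows <- list()
  for (i in seq_along(factors)) {
    for (r in seq_len(runs_per_step)) {
      seed <- derive_seed(base_seed, (i - 1) * runs_per_step + r)
      fit <- fit_parameters(observations, drivers, bounds, seed = seed,
                            fixed = c(f_gs_night = factors[i]),
                            control = control, sd_band = sd_band)
      rows[[length(rows) + 1]] <- data.frame(
        factor = factors[i], run = r, seed = seed,
        error = fit$objective, accepted = fit$accepted
      )
    }
  }
  results <- do.call(rbind, rows)
  med <- vapply(factors, function(f) {
    stats::median(results$error[results$factor == f])
  }, 0)
  acc <- vapply(factors, function(f) {
    sum(results$accepted[results$factor == f], na.rm = TRUE)
  }, 0)
  summary <- data.frame(factor = factors, median_error = med, accepted = acc)
  structure(list(results = results, summary = summary,
                 best_factor = factors[which.min(med)],
                 base_seed = base_seed),
            class = "cn_gs_scan")
}

#' @export
print.cn_gs_scan <- function(x, ...) {
  cat("<cn_gs_scan> error-minimizing nocturnal GS factor:", x$best_factor, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract reaction fluxes from a fitted ensemble
#'
#' Evaluates the full flux vector along each member's fitted trajectory at
#' the requested harvest times.
#'
#' @param ensemble A `cn_ensemble`.
#' @param drivers The driver set the ensemble was fitted under.
#' @param times Times of day (h) on the members' trajectory grid.
#' @return Tidy data frame: `run, time_h, flux, value_umol_per_gFW_per_h`.
#' @export
extract_fluxes <- function(ensemble, drivers, times = NULL) {
  grid <- ensemble$fits[[1]]$trajectory$time_h
  if (is.null(times)) times <- grid
  if (any(times < 0 | times >= 24)) stop("validation error: times must lie in [0, 24)")
  if (!all(times %in% grid)) stop("validation error: times must be on the fitted grid")
  do.call(rbind, lapply(seq_along(ensemble$fits), function(i) {
    f <- ensemble$fits[[i]]
    wide <- trajectory_fluxes(f$trajectory, f$params, drivers, times = times)
    long <- tidy_fluxes(wide, condition = NA_character_, run_id = i)
    data.frame(run = long$run_id, time_h = long$time_h, flux = long$flux,
               value_umol_per_gFW_per_h = long$value_umol_per_gFW_per_h)
  }))
}

#' Flux ratios during the light phase
#'
#' NR/GDC and HP2BMEXP/NR per run and light-phase time point. Rows whose
#' denominator falls below `eps` are excluded and counted.
#'
#' @param flux_table Tidy flux table from [extract_fluxes()].
#' @param light_hours Length of the light phase (h).
#' @param eps Denominator guard (umol g-1 FW h-1).
#' @return Data frame `run, time_h, ratio, value` (ratio in
#'   {"NR/GDC", "HP2BMEXP/NR"}) with attribute `n_excluded`; a warning is
#'   emitted when every row is excluded.
#' @export
flux_ratios <- function(flux_table, light_hours = 8, eps = 1e-6) {
  ft <- flux_table[flux_table$time_h < light_hours, , drop = FALSE]
  wide <- stats::reshape(
    ft[ft$flux %in% c("v_nr", "v_gdc", "v_hp2bmexp"), ],
    idvar = c("run", "time_h"), timevar = "flux", direction = "wide"
  )
  names(wide) <- sub("^value_umol_per_gFW_per_h\\.", "", names(wide))
  build <- function(num, den, label) {
    ok <- wide[[den]] >= eps
    data.frame(run = wide$run[ok], time_h = wide$time_h[ok],
               ratio = rep(label, sum(ok)),
               value = wide[[num]][ok] / wide[[den]][ok],
               stringsAsFactors = FALSE)
  }
  out <- rbind(build("v_nr", "v_gdc", "NR/GDC"),
               build("v_hp2bmexp", "v_nr", "HP2BMEXP/NR"))
  n_excluded <- 2L * nrow(wide) - nrow(out)
  if (nrow(out) == 0) warning("empty result: all ratio rows excluded")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Median ratio summary across runs
#'
#' @param ratios Output of [flux_ratios()].
#' @return Data frame `ratio, time_h, median, q25, q75, n`.
#' @export
summarize_ratios <- function(ratios) {
  sp <- split(ratios, list(ratios$ratio, ratios$time_h), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(ratio = d$ratio[1], time_h = d$time_h[1],
               median = stats::median(d$value),
               q25 = stats::quantile(d$value, 0.25, names = FALSE),
               q75 = stats::quantile(d$value, 0.75, names = FALSE),
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$ratio, out$time_h), ]
}
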