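#' Time-dependent driver construction
#'
#' The model is driven by measured externals: a diurnal photosynthesis curve
#' interpolated from gas-exchange measurements, a constant dark respiration,
#' and diurnal splines through four enzyme-activity measurements (NR, GS,
#' HPR). All drivers are periodic with period 24 h; t = 0 is light-on, the
#' light phase is `[0, light_hours)` and the dark phase the remainder.
#'
#' @name drivers
NULL

#' Photosynthesis spline from a gas-exchange series
#'
#' Builds a periodic net-CO2-exchange function: a natural cubic spline through
#' the light-phase measurements, and exactly `-rd` throughout the dark phase
#' (net exchange at night is respiration only).
#'
#' @param series Data frame with columns `time_h` (ascending, in `[0, 24)`)
#'   and `flux` (umol g-1 FW h-1).
#' @param rd Dark respiration magnitude (positive).
#' @param light_hours Length of the light phase (h), default 8.
#' @return Function `ps(t)` accepting a numeric vector of hours.
#' @export
build_ps_spline <- function(series, rd, light_hours = 8) {
  stopifnot(is.data.frame(series), all(c("time_h", "flux") %in% names(series)))
  if (rd < 0) stop("invalid driver: rd must be a positive magnitude")
  s <- series[order(series$time_h), , drop = FALSE]
  if (any(s$time_h < 0) || any(s$time_h >= 24)) stop("times must lie in [0, 24)")
  light <- s[s$time_h < light_hours, , drop = FALSE]
  if (nrow(light) < 4) stop("insufficient data: need at least 4 light-phase points")
  fl <- stats::splinefun(light$time_h, light$flux, method = "natural")
  force(rd); force(light_hours)
  function(t) {
    tt <- t %% 24
    ifelse(tt < light_hours, fl(tt), -rd)
  }
}

#' Enzyme-activity spline through four diurnal measurements
#'
#' Activities are measured at the beginning, middle and end of the light phase
#' and in the middle of the night (t = 0, 4, 8, 16 h for an 8-h day) and
#' interpolated with a shape-preserving monotone cubic (no negative
#' overshoot; values stay within the node range between nodes). The curve is
#' closed periodically by repeating the t = 0 value at t = 24. For GS, an
#' optional multiplicative factor down-regulates the dark-phase value.
#'
#' @param series Data frame with columns `time_h` and `vmax` (>= 0); exactly
#'   four nodes.
#' @param f_night Multiplier applied in the dark phase (default 1; use the
#'   fitted nocturnal GS factor for GS).
#' @param light_hours Length of the light phase (h), default 8.
#' @return Function `vmax(t)`.
#' @export
build_vmax_spline <- function(series, f_night = 1, light_hours = 8) {
  stopifnot(is.data.frame(series), all(c("time_h", "vmax") %in% names(series)))
  if (nrow(series) != 4) stop("activity series must have exactly 4 nodes")
  if (any(series$vmax < 0)) stop("validation error: negative enzyme activity")
  s <- series[order(series$time_h), , drop = FALSE]
  tt <- c(s$time_h, 24)
  vv <- c(s$vmax, s$vmax[1])
  f <- stats::splinefun(tt, vv, method = "monoH.FC")
  # the Fritsch-Carlson filter can overshoot marginally around the periodic
  # closure node; clamp to the node range so values never leave it
  lo <- min(vv); hi <- max(vv)
  force(f_night); force(light_hours)
  function(t) {
    tm <- t %% 24
    pmin(pmax(f(tm), lo), hi) * ifelse(tm < light_hours, 1, f_night)
  }
}

#' Assemble the driver set
#'
#' @param ps Photosynthesis function from [build_ps_spline()].
#' @param rd Constant dark respiration magnitude (umol g-1 FW h-1).
#' @param vmax_nr,vmax_gs,vmax_hpr Activity splines from
#'   [build_vmax_spline()]; `vmax_gs` holds the raw in vitro curve (the
#'   nocturnal factor is a fitted parameter applied at flux evaluation).
#' @param co2 Growth CO2 concentration (ppm).
#' @param gamma_star CO2 compensation point (ppm).
#' @param no3_total Total foliar nitrate content (umol g-1 FW).
#' @param light_hours Light-phase length (h), default 8.
#' @param per_cytosol_volume Nitrate volume convention, see
#'   [cytosolic_nitrate()].
#' @param gate_carboxylates Phase-gate the Cit/MF interconversions (MF -> Cit
#'   only in the dark, Cit -> alpha-KG only in the light); default TRUE.
#' @return An object of class `cn_drivers`.
#' @export
driver_set <- function(ps, rd, vmax_nr, vmax_gs, vmax_hpr,
                       co2, gamma_star, no3_total,
                       light_hours = 8, per_cytosol_volume = FALSE,
                       gate_carboxylates = TRUE) {
  stopifnot(is.function(ps), is.function(vmax_nr), is.function(vmax_gs),
            is.function(vmax_hpr))
  if (co2 <= 0) stop("invalid driver: co2 must be > 0")
  if (gamma_star < 0) stop("invalid driver: gamma_star must be >= 0")
  if (rd < 0 || no3_total < 0) stop("invalid driver: rd and no3_total must be >= 0")
  structure(list(
    ps = ps, rd = rd,
    vmax_nr = vmax_nr, vmax_gs = vmax_gs, vmax_hpr = vmax_hpr,
    co2 = co2, gamma_star = gamma_star, no3_total = no3_total,
    light_hours = light_hours,
    per_cytosol_volume = per_cytosol_volume,
    gate_carboxylates = gate_carboxylates,
    phi = oxygenation_ratio(gamma_star, co2),
    no3_cyt = cytosolic_nitrate(no3_total, per_cytosol_volume),
    cache = new.env(parent = emptyenv())
  ), class = "cn_drivers")
}

#' Is it light at time t?
#'
#' @param t Hours (vectorised); taken modulo 24.
#' @param light_hours Light-phase length.
#' @return Logical vector.
#' @export
is_light <- function(t, light_hours = 8) (t %% 24) < light_hours

#' @export
print.cn_drivers <- function(x, ...) {
  cat("<cn_drivers>\n",
      sprintf("  CO2 %g ppm, gamma* %g ppm (Phi = %.3f)\n", x$co2, x$gamma_star, x$phi),
      sprintf("  rd %g umol/gFW/h, nitrate %g umol/gFW (cytosolic %.3f mM)\n",
              x$rd, x$no3_total, x$no3_cyt),
      sprintf("  light 0-%g h, dark %g-24 h\n", x$light_hours, x$light_hours),
      sep = "")
  invisible(x)
}

#' Read gas-exchange and activity CSV files
#'
#' `read_gas_exchange()` expects columns `time_h, flux`;
#' `read_activities()` expects `enzyme, time_h, vmax` with enzymes NR, GS and
#' HPR, four nodes each.
#'
#' @param path CSV file path.
#' @return Data frame (activities: split into a named list of data frames).
#' @export
read_gas_exchange <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_h", "flux")
  if (!all(need %in% names(d))) {
    stop("gas-exchange file must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_gas_exchange
#' @export
read_activities <- function(path) {
  d <- utils::read.csv(path)
  need <- c("enzyme", "time_h", "vmax")
  if (!all(need %in% names(d))) {
    stop("activities file must have columns: ", paste(need, collapse = ", "))
  }
  out <- split(d[c("time_h", "vmax")], d$enzyme)
  miss <- setdiff(c("NR", "GS", "HPR"), names(out))
  if (length(miss)) stop("activities file missing enzyme(s): ", paste(miss, collapse = ", "))
  out
}
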