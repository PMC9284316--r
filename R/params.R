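#' Kinetic parameter vector
#'
#' All fitted constants of the diurnal C/N model. Michaelis constants are in
#' mM, unmeasured maximum rates in umol g-1 FW h-1, mass-balance constants in
#' h-1. `alpha` is the dark photorespiration summand (umol g-1 FW h-1),
#' `correct` the fraction of the NR flux routed from Glu into the free
#' amino-acid pool (in `[0.5, 1]`), `f_gs_night` the multiplicative nocturnal
#' down-regulation of GS vmax (in `(0, 1]`), and `s_day` the linear starch
#' synthesis rate during the light phase (hexose equivalents).
#'
#' @param ... Named parameter values overriding the defaults.
#' @param values Optionally a full named numeric vector.
#' @return An object of class `cn_params` (named numeric vector).
#' @export
kinetic_params <- function(..., values = NULL) {
  p <- default_params()
  over <- if (is.null(values)) c(...) else values
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "cn_params")
}

param_names <- function() {
  c("km_gdc", "km_shmt", "km_hpr", "km_gs_nh4", "km_gs_glu",
    "km_gogat_gln", "km_gogat_kg", "km_nr",
    "vmax_gdc", "vmax_shmt", "vmax_gogat",
    "k_hp2bmexp", "k_hp2mf", "k_mf2cit", "k_cit2mf", "k_cit2kg",
    "k_ser2aa", "k_aa2bmexp",
    "alpha", "correct", "f_gs_night", "s_day")
}

validate_params <- function(p) {
  stopifnot(is.numeric(p))
  miss <- setdiff(param_names(), names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p))) stop("parameters must be finite")
  kms <- grep("^km_", names(p), value = TRUE)
  if (any(p[kms] <= 0)) stop("invalid parameter: km values must be > 0")
  nonneg <- setdiff(names(p), kms)
  if (any(p[nonneg] < 0)) stop("invalid parameter: rates must be >= 0")
  if (p[["correct"]] < 0.5 || p[["correct"]] > 1) {
    stop("invalid parameter: correct must lie in [0.5, 1]")
  }
  if (p[["f_gs_night"]] <= 0 || p[["f_gs_night"]] > 1) {
    stop("invalid parameter: f_gs_night must lie in (0, 1]")
  }
  invisible(p)
}

#' Default (ground-truth) parameter table
#'
#' The versioned default parameterisation used by the synthetic-data
#' generator. Values are chosen to give diurnal pool sizes and fluxes of the
#' order observed in Arabidopsis rosettes (photorespiratory input around a
#' quarter of net assimilation at ambient CO2, free amino acids tens of
#' umol g-1 FW, hexose phosphates around 1 umol g-1 FW); they are
#' order-of-magnitude placeholders, not measured values.
#'
#' @return A `cn_params` vector.
#' @export
default_params <- function() {
  structure(c(
    km_gdc = 5.5, km_shmt = 4.0, km_hpr = 0.8,
    km_gs_nh4 = 1.0, km_gs_glu = 6.0,
    km_gogat_gln = 0.8, km_gogat_kg = 0.15, km_nr = 0.3,
    vmax_gdc = 40, vmax_shmt = 30, vmax_gogat = 30,
    k_hp2bmexp = 5.0, k_hp2mf = 1.2, k_mf2cit = 0.03,
    k_cit2mf = 0.02, k_cit2kg = 0.12,
    k_ser2aa = 0.2, k_aa2bmexp = 0.06,
    alpha = 0.8, correct = 0.7, f_gs_night = 0.35, s_day = 6
  ), class = "cn_params")
}

#' Default optimisation bounds
#'
#' A box around the default parameter table: multiplicative `spread` below and
#' above each default (0.5x to 1.5x by default), intersected with the hard
#' ranges `correct` in `[0.5, 1]` and `f_gs_night` in `(0, 1]`.
#'
#' @param params Centre of the box (default [default_params()]).
#' @param spread Half-width as a fraction of the centre value (default 0.5).
#' @return Data frame with columns `parameter`, `lower`, `upper`.
#' @export
default_bounds <- function(params = default_params(), spread = 0.5) {
  p <- unclass(params)[param_names()]
  b <- data.frame(
    parameter = names(p),
    lower = p * (1 - spread),
    upper = p * (1 + spread),
    row.names = NULL
  )
  clamp <- function(name, lo, hi) {
    i <- b$parameter == name
    b$lower[i] <<- max(b$lower[i], lo)
    b$upper[i] <<- min(b$upper[i], hi)
  }
  clamp("correct", 0.5, 1)
  clamp("f_gs_night", 0.05, 1)
  km <- grepl("^km_", b$parameter)
  b$lower[km] <- pmax(b$lower[km], 1e-6)
  b
}

validate_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("parameter", "lower", "upper") %in% names(bounds)))
  miss <- setdiff(param_names(), bounds$parameter)
  if (length(miss)) stop("bounds missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper))) {
    stop("bounds must be finite")
  }
  if (any(bounds$upper < bounds$lower)) stop("bounds must satisfy lower <= upper")
  invisible(bounds)
}

#' @export
print.cn_params <- function(x, ...) {
  cat("<cn_params> diurnal C/N model parameters\n")
  print(round(unclass(x), 4))
  invisible(x)
}
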