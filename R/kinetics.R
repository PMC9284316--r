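#' Elementary rate laws and gas-exchange arithmetic
#'
#' These are the building blocks of the diurnal C/N network: single-substrate
#' Michaelis-Menten kinetics, first-order mass-balance kinetics, and the
#' photorespiration input derived from net CO2 exchange via the
#' oxygenation-to-carboxylation ratio.
#'
#' @name kinetics
NULL

#' Michaelis-Menten rate
#'
#' @param s Substrate concentration (mM), non-negative. Vectorised.
#' @param vmax Maximum rate (umol g-1 FW h-1), non-negative.
#' @param km Half-saturation constant (mM), strictly positive.
#' @return Rate `vmax * s / (km + s)`, bounded above by `vmax`.
#' @examples
#' michaelis_menten(2, 10, 2)  # half saturation -> 5
#' @export
michaelis_menten <- function(s, vmax, km) {
  if (any(km <= 0)) stop("invalid parameter: km must be > 0")
  if (any(s < 0) || any(vmax < 0)) stop("invalid parameter: s and vmax must be >= 0")
  vmax * s / (km + s)
}

#' First-order mass-balance rate
#'
#' @param s Donor pool content (umol g-1 FW), non-negative.
#' @param k First-order rate constant (h-1), non-negative.
#' @return Rate `k * s`.
#' @export
mass_balance <- function(s, k) {
  if (any(s < 0) || any(k < 0)) stop("invalid parameter: s and k must be >= 0")
  k * s
}

#' Oxygenation-to-carboxylation ratio
#'
#' Ratio of Rubisco oxygenation to carboxylation, `Phi = 2 * gamma_star / C`,
#' with the CO2 compensation point `gamma_star` and the CO2 concentration at
#' the site of carboxylation in the same units (here: ppm of growth CO2).
#'
#' @param gamma_star CO2 compensation point (ppm), non-negative.
#' @param c_co2 CO2 concentration (ppm), strictly positive.
#' @return Dimensionless ratio Phi.
#' @export
oxygenation_ratio <- function(gamma_star, c_co2) {
  if (any(c_co2 <= 0)) stop("invalid driver: CO2 concentration must be > 0")
  if (any(gamma_star < 0)) stop("invalid driver: gamma_star must be >= 0")
  2 * gamma_star / c_co2
}

#' Rubisco oxygenation rate from net gas exchange
#'
#' `v_o = (A_net + R_d) / (1/Phi - 0.5)`. Respiration is passed as a positive
#' magnitude and added to net assimilation; in the dark `A_net = -R_d` and the
#' numerator (gross assimilation) vanishes. A negative numerator is clamped to
#' zero, as is the `Phi = 0` limit.
#'
#' @param a_net Net CO2 exchange (umol g-1 FW h-1), signed.
#' @param rd Dark respiration magnitude (umol g-1 FW h-1), non-negative.
#' @param phi Oxygenation-to-carboxylation ratio in `[0, 1]`.
#' @return Oxygenation rate v_o (umol g-1 FW h-1), non-negative.
#' @export
oxygenation_rate <- function(a_net, rd, phi) {
  if (any(rd < 0)) stop("invalid parameter: rd must be >= 0")
  if (any(phi < 0) || any(phi > 1)) {
    stop("invalid parameter: phi must lie in [0, 1]")
  }
  num <- a_net + rd
  out <- ifelse(phi > 0, num / (1 / phi - 0.5), 0)
  pmax(out, 0)
}

#' Photorespiratory flux entering the model
#'
#' Half the oxygenation rate during the light phase (two 2-phosphoglycolate
#' per oxygenation cycle yield one serine-bound unit entering as glycine),
#' plus a constant summand `alpha` that keeps the pathway turning over in the
#' dark, where the gas-exchange-derived term is zero.
#'
#' @param v_o Oxygenation rate (umol g-1 FW h-1), non-negative.
#' @param alpha Dark photorespiration summand (umol g-1 FW h-1), non-negative.
#' @param is_light Logical, TRUE during the light phase.
#' @return v_pr (umol g-1 FW h-1).
#' @export
pr_flux <- function(v_o, alpha, is_light) {
  if (any(v_o < 0) || any(alpha < 0)) stop("invalid parameter: v_o and alpha must be >= 0")
  ifelse(is_light, v_o / 2, 0) + alpha
}

#' SHMT rate, capped by the GDC rate
#'
#' Serine hydroxymethyltransferase consumes the C1 unit produced by glycine
#' decarboxylase, so its turnover cannot exceed GDC's.
#'
#' @param gly_conc Glycine concentration (mM).
#' @param vmax_shmt,km_shmt SHMT kinetic constants.
#' @param v_gdc GDC rate (umol g-1 FW h-1), non-negative.
#' @return `min(MM(gly), v_gdc)`.
#' @export
shmt_flux <- function(gly_conc, vmax_shmt, km_shmt, v_gdc) {
  if (any(v_gdc < 0)) stop("invalid parameter: v_gdc must be >= 0")
  pmin(michaelis_menten(gly_conc, vmax_shmt, km_shmt), v_gdc)
}

#' Glutamate-to-alpha-ketoglutarate flux from the N1 balance
#'
#' The photorespiratory glycine influx, the HPR flux and the Glu -> alpha-KG
#' flux are all single-nitrogen fluxes; balancing them gives
#' `v_glu2kg = max(v_pr - v_hpr, 0)`.
#'
#' @param v_pr,v_hpr Fluxes (umol g-1 FW h-1), non-negative.
#' @return Non-negative flux.
#' @export
glu2kg_flux <- function(v_pr, v_hpr) {
  if (any(v_pr < 0) || any(v_hpr < 0)) stop("invalid parameter: fluxes must be >= 0")
  pmax(v_pr - v_hpr, 0)
}

#' Convert tissue content to concentration
#'
#' Assumes 1 g fresh weight occupies 0.77 ml, so a content in umol g-1 FW
#' divided by 0.77 ml g-1 gives mM.
#'
#' @param content Content (umol g-1 FW), non-negative.
#' @return Concentration (mM).
#' @export
content_to_concentration <- function(content) {
  if (any(content < 0)) stop("invalid parameter: content must be >= 0")
  content / .tissue_volume_ml_per_g
}

.tissue_volume_ml_per_g <- 0.77
.cytosol_fraction <- 0.05

#' Cytosolic nitrate concentration available to nitrate reductase
#'
#' Most foliar nitrate is vacuolar and inaccessible to NR; only the cytosolic
#' share (about 5 % of cell volume) is taken as substrate. By default the 5 %
#' amount fraction is diluted in the total tissue volume (0.77 ml g-1); set
#' `per_cytosol_volume = TRUE` to instead place the 5 % amount in 5 % of the
#' volume (full-concentration convention).
#'
#' @param no3_total Total foliar nitrate (umol g-1 FW).
#' @param per_cytosol_volume Volume convention switch (default FALSE).
#' @return Concentration (mM) seen by NR.
#' @export
cytosolic_nitrate <- function(no3_total, per_cytosol_volume = FALSE) {
  if (any(no3_total < 0)) stop("invalid parameter: no3_total must be >= 0")
  amount <- .cytosol_fraction * no3_total
  vol <- if (per_cytosol_volume) .cytosol_fraction * .tissue_volume_ml_per_g else .tissue_volume_ml_per_g
  amount / vol
}
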