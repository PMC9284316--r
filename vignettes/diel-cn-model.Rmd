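---
title: "A diurnal kinetic model of photorespiratory carbon and nitrogen assimilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A diurnal kinetic model of photorespiratory carbon and nitrogen assimilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielCN)
```

## The model

`dielCN` simulates ten metabolite pools in leaf tissue over a 24-h light/dark
cycle: glycine, serine, hexose phosphates (C6 equivalents), malate + fumarate,
citrate, alpha-ketoglutarate, glutamate, glutamine, the remaining free
amino-acid pool, and ammonium. Everything else — O2, CO2, biomass, starch,
exported assimilate, and nitrate — sits outside the system boundary: its
exchange *rates* enter the equations, but its amounts are not tracked.

Carbon enters through net photosynthesis. The photorespiratory branch is not
resolved reaction by reaction; instead the whole stretch from RuBP oxygenation
to glyoxylate amination is collapsed into a single influx that delivers
glycine. Its rate follows from gas exchange: the oxygenation-to-carboxylation
ratio is

$$\Phi = \frac{2\,\Gamma^{*}}{C},$$

with the CO2 compensation point $\Gamma^*$ and the CO2 concentration $C$ at
the site of carboxylation (approximated here by the growth CO2 level, 450 or
1000 ppm; $\Gamma^*$ is a configuration input). The oxygenation rate is

$$v_o = \frac{A_{net} + R_d}{1/\Phi - 0.5},$$

where respiration $R_d$ is stored as a positive magnitude and *added* to net
assimilation — a printed subtraction corresponds to recording respiration as a
negative flux. The glycine influx is $v_{PR} = v_o/2 + \alpha$ in the light
and $\alpha$ in the dark: half an oxygenation event per glycine, plus a
constant summand $\alpha$ that lets the pathway keep turning over at night
(serine turnover demonstrably continues after light-off, most prominently in
HPR-deficient plants). Each $v_{PR}$ unit carries one glycine (one nitrogen);
a factor-of-two bookkeeping (two glycines per oxygenation cycle) would be
equally defensible but is intentionally not applied, because the N1-flux
balance below absorbs the convention.

### Rate laws

Fluxes named by the network's mass-balance assignment are first order in
their donor pool: HP to biomass/export, HP to malate+fumarate, the
malate/citrate interconversions, citrate to alpha-KG, serine to the
amino-acid pool, and amino acids to biomass/export. The enzymatic steps are
Michaelis–Menten: GDC and SHMT on glycine (with SHMT capped at the GDC rate,
since SHMT consumes the C1 unit GDC produces), HPR on serine, NR on the
cytosolic nitrate fraction, GS as a two-substrate multiplicative form in
ammonium and glutamate, and GOGAT as a two-substrate form in glutamine and
alpha-KG. The multiplicative two-substrate form is the simplest saturable
choice for the two bi-substrate reactions. Measured maximum activities drive
NR, GS and HPR as diurnal splines; GDC, SHMT and GOGAT capacities are fitted
constants.

Three fluxes are derived rather than kinetic. The photorespiratory glycine
influx, the HPR flux and the glutamate-to-alpha-KG flux are all
single-nitrogen fluxes, so they balance:
$v_{glu2kg} = \max(v_{PR} - v_{HPR}, 0)$. Nitrate reductase is the only source
of de novo nitrogen, and its product is routed to the amino-acid pool as
$v_{glu2aa} = \mathrm{correct} \cdot v_{NR}$ with
$\mathrm{correct} \in [0.5, 1]$ (about half of serine nitrogen is newly
assimilated, so the complement deposits in the photorespiratory pools).
Glycine and serine cannot reach biomass through the bulk amino-acid route, so
a dedicated serine drain is tied to it:
$v_{ser2bm} = 0.14\, v_{aa2bmexp}$ (the serine share of Rubisco, the dominant
leaf protein).

### Stoichiometry and units

All pools are in µmol of metabolite per g fresh weight; concentrations for
Michaelis–Menten terms divide by the tissue volume of 0.77 ml g⁻¹ FW.
Nitrate is compartmented: only about 5 % of cell volume is cytosol, so NR
sees 5 % of the foliar nitrate amount, diluted — by default — in the total
tissue volume. (Whether the 5 % amount should instead sit at full
concentration in 5 % of the volume is not decidable from the phrasing the
design is based on; the alternative is exposed as the `per_cytosol_volume`
switch and changes only the effective NR saturation.)

Carbon conversion factors keep both element balances closed and testable:
the HP pool is in hexose units, so the photosynthetic input contributes
$(A_{net} + R_d + v_{GDC} - 2 v_{PR})/6$ (adding back the GDC-released CO2
already netted out of $A_{net}$, and removing the two carbons leaving into
glycine), HPR returns 0.5 HP per serine (3C glycerate into a C6 pool), one HP
makes 1.5 malate equivalents, 1.5 malate make one citrate, one citrate makes
1.2 alpha-KG, and respiration drains malate at $R_d/4$ (a C4 acid fully
oxidized). GDC releases one CO2 and one C1 unit per glycine; the C1 pool is
not modelled, and the C1 not consumed by SHMT is treated as an external leak.
The free amino-acid pool is tracked in nitrogen units, so its two inflows
(3C from serine, 5C from glutamate) count as carbon exports at the boundary.

Starch exchange is linear: synthesis at a fitted constant rate `s_day`
during the 8-h light phase and degradation at `s_day`·8/16 during the 16-h
dark phase, so the daily starch budget closes. Citrate dynamics are
phase-gated by default (`gate_carboxylates`): malate-to-citrate runs only in
the dark and citrate-to-alpha-KG only in the light, reflecting the
observation that citrate accumulates nocturnally and fuels daytime alpha-KG
production; the ungated variant is a configuration switch.

## Drivers

Net CO2 exchange is measured quasi-continuously; a natural cubic spline
through the light-phase points represents the photosynthesis curve, and the
dark phase is pinned at exactly $-R_d$ (dark respiration, measured in the
dark phase, is held constant over the whole cycle). Enzyme activities are
measured four times per cycle — begin, middle and end of the light phase and
the middle of the night, placed at t = 0, 4, 8 and 16 h — and interpolated
with a shape-preserving monotone cubic so the curve can neither overshoot
negative nor leave the node range between nodes. All drivers are periodic
with period 24 h; t = 0 is light-on.

The nocturnal GS factor `f_gs_night` multiplies the *in vitro* GS activity
spline in the dark phase only. It is a fitted parameter (or a scanned
constant), not part of the measured driver: reductant added during protein
extraction keeps the plastidial GS isoform fully activated in the assay, so
the bench value overestimates the nocturnal in vivo capacity.

## Parameter estimation

The objective is the averaged relative deviation, in percent per state and
time point:
$100 \cdot \mathrm{mean}\,|y_{sim} - \bar y_{obs}| / \max(\bar y_{obs}, \varepsilon)$
with $\varepsilon = 10^{-3}$ µmol g⁻¹ FW flooring near-zero means. Only the
t = 0 observation means seed the simulation; all later time points constrain
the fit. The optimizer is a global-best particle swarm (constriction
coefficients 0.7298/1.49618, Latin-hypercube initial positions, velocities
clamped to half the box width, reflection at the bounds) — a
population-based search suits the multimodal, derivative-free landscape, and
every run is reproducible from its seed.
Integration failures during the search are penalized rather than fatal. A
fit is *accepted* when every state lies within the measured standard
deviation at every time point (a `sd_band` multiplier generalizes the band
for synthetic regimes). Ensembles run independently seeded fits (the
study-scale convention is 20) and report the member fits, the arithmetic
mean trajectory and the acceptance count.

Because a broad HPR Km interval lets an optimizer compensate a genetically
lowered vmax with an unrealistically low Km, mutant fits take the minimum Km
identified across the wildtype ensemble as their lower bound
(`hpr_km_bound()`), optionally relaxed by a further 30 %.

## The synthetic study

`generate_dataset()` emulates the measurement design end to end: four
conditions (wildtype and an HPR-deficient mutant at 450 and 1000 ppm CO2),
light-phase mean photosynthesis of 85.4, 128.1, 76.8 and 98.6
µmol g⁻¹ FW h⁻¹ respectively, an 8 h/16 h photoperiod, harvests every 2 h at
five replicates, and activity series at the four standard nodes. The
gas-exchange curve is a smooth arch (square root of a sine: fast post-dawn
rise, flattened top) anchored at $-R_d$ at both light transitions and scaled
to the condition mean. Replicate noise is multiplicative lognormal with a
configurable coefficient of variation (default 0.1, assay-like
heteroscedasticity), fully seeded. The mutant is emulated *solely* by
scaling the HPR activity curve to 10 % — the lesion the model represents —
and its serine pool then accumulates roughly tenfold over the wildtype by
end of day as an emergent consequence. The generator's forward simulation
applies the ground-truth `f_gs_night` to the dark-phase GS capacity while the
written activity CSV carries the in vitro values, exactly the mismatch the
inactivation scan is designed to detect.

Ground-truth parameters and initial pools are order-of-magnitude choices
documented in `default_params()` — photorespiratory input near a quarter of
net assimilation at ambient CO2, nitrate assimilation near 1 µmol g⁻¹ FW h⁻¹
against a realistic rosette N demand, free amino acids in the tens of
µmol g⁻¹ FW — not reproductions of any measured series. Two structural
consequences are worth knowing when reading synthetic trajectories: with the
carboxylate gate closed at night there is no nocturnal alpha-KG source, so
GOGAT stalls after dusk and glutamate declines through the night until its
consumers are gated off; and the glutamine pool inflates correspondingly.
Both mirror the qualitative night-time behaviour the nocturnal GS
down-regulation was introduced to repair, and both limit how literally the
night-phase synthetic pools should be compared to real measurements.

## Numerical choices

* Integration uses `deSolve::lsoda` (adaptive, stiff-capable), restarted at
  the light/dark transition so the driver discontinuity is never stepped
  over; default tolerances are `rtol = 1e-6`, `atol = 1e-10` (`1e-8` inside
  the optimizer loop).
* The production right-hand side is compiled C; the four driver curves are
  sampled onto a uniform 0.01-h grid and linearly interpolated in C. The
  interpreted R path (`engine = "R"`) evaluates the splines exactly and
  serves as a cross-check; the two agree to well under 0.1 % except within
  the dusk transient on pools that are crashing to zero there.
* Rate laws vanish at zero substrate. Five fluxes whose rate law does not
  contain their donor pool (the derived Glu and Ser drains, respiration and
  light-phase starch synthesis) carry a smooth depletion gate
  $s/(s + 10^{-4})$ so the integrator is never pushed below zero; the gate
  deviates from the exact derived-flux identities by at most
  $10^{-4}/\mathrm{pool}$. Residual negative excursions within 10⁻⁶
  µmol g⁻¹ FW of zero (far below anything measurable) are zeroed silently;
  larger ones are clipped with a warning, and macroscopic (>10⁻⁴) or
  persistent (>0.1 % of values) clipping fails the run.
* The 12-point 2-h observation grid is the default (an 8-point variant is a
  configuration choice); ensembles default to 20 members at study scale,
  while the shipped tests and the reproduction script use 5–20 fits with a
  24-particle, 50–80-iteration swarm — problem sizes chosen so a complete
  check runs comfortably on a laptop core while leaving the optimizer
  converged enough for the recovery properties to hold.

## Known limitations

* Individual photorespiratory intermediates (2-PG, glycolate, glyoxylate),
  the C1/THF pool, and compartment-resolved transport are outside scope by
  construction; the mutant's hypothesized extra glycolate source is likewise
  not modelled, so mutant *glycine* does not rise above wildtype in forward
  simulations even though serine does.
* The objective floor on noisy data is set by the replicate sampling error of
  the observation means (≈ cv·√(2/(5π))·100 % per cell, plus the noisy t = 0
  initialisation), not by the optimizer; fit-quality numbers should be read
  against that floor.
* Acceptance against a 1-SD band at every cell is strict: with five
  replicates a well-converged fit still fails occasionally on a single
  unlucky cell, and near-zero cells make the band essentially unattainable;
  the `sd_band` multiplier exists for exactly that reason.
* The nocturnal GS factor is identifiable only through the nocturnal
  ammonium/glutamine levels; its signal survives re-optimization of all
  other parameters but is a one-to-few-percentage-point effect, which is why
  the scan uses medians over repeated fits.

## A minimal session

```{r example, eval = FALSE}
spec <- default_condition_specs()[["Col-0_ambient"]]
sim <- simulate_condition(spec)
obs <- sample_replicates(sim$trajectory, n = 5, cv = 0.05, seed = 42)
ens <- run_ensemble(obs, sim$drivers, default_bounds(), n_runs = 5,
                    base_seed = 7, control = pso_control())
ens
fluxes <- extract_fluxes(ens, sim$drivers, times = c(2, 4, 6))
summarize_ratios(flux_ratios(fluxes))
```
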