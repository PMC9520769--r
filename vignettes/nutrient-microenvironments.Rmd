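---
title: "Modeling nutrient microenvironments in NP cell culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nutrient microenvironments in NP cell culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nucleus pulposus (NP) cells live in an avascular tissue where oxygen,
glucose and lactate move only by diffusion, so the concentrations a cell
actually experiences in vitro can differ substantially from the incubator
setting and the bottle label on the media. `npmicroenv` computes those
local concentrations for the culture systems NP groups actually use —
monolayer expansion in plates and flasks, 30 ul alginate beads,
cylindrical hydrogel constructs, and pellet/microaggregate cultures — so
that experiments can be designed around the microenvironment the cells
see rather than the one the incubator is set to.

## Model

### Boundary conditions

A humidified 5% CO~2~ incubator dilutes oxygen relative to dry gas: the
oxygen partial pressure is `o2_fraction * (P - pCO2 - pH2O)` with
defaults 760, 38 and 47 mmHg.  Henry's law (solubility 1.3 uM/mmHg at
37 C) converts this to the dissolved concentration imposed at the media
free surface: 183.8 uM for normoxia (NX, 20.95% dry gas), 43.9 uM for
physioxia (PX, 5%), 17.6 uM for hypoxia (HX, 2%).  Results are reported
both in uM and in "%O2" — the gas-phase percentage of total pressure
whose equilibrium dissolved level equals the local concentration,
`uM / (1.3 * 7.6)` — because that is the unit the field reports.  Oxygen
is fixed only at the free surface; vessel plastic is effectively
impermeable on these time scales, so every other boundary is no-flux, and
glucose and lactate see a closed vessel between media exchanges.

### Metabolism

Per-cell rates (nmol per 10^6 cells per hour) follow the compiled
disc-cell kinetics, keyed by the external regime:

* **OCR** — pH- and oxygen-dependent Michaelis-Menten respiration,
  `Vmax * (pH - 4.95) * C / (Km * (pH - 4.95) + C)` with Vmax 17
  (animal/healthy) or 62 (degenerated human) and Km 12 uM.  Two points
  deserve emphasis.  First, the published lineage of this law prints the
  denominator offset once as 4.59; we treat that as a typographical
  variant of the single 4.95 offset, which changes Km by under 15% and
  the solved fields by far less.  Second, the pH factor is applied
  *literally*, so the realized saturating rate at the reference pH 7.4 is
  `2.45 * Vmax`, not Vmax.  The package also provides
  `ocr_ph_form = "normalized"`, which rescales the pH factor so the
  tabulated Vmax is itself the saturating rate at pH 7.4.  We verified
  both variants against the reported bead, cylinder, pellet and monolayer
  oxygen minima: the literal form reproduces them closely at every
  seeding density and phenotype, while the normalized form underestimates
  every oxygen drop by roughly half.  The literal form is therefore the
  default.
* **GCR** — `Vmax * C / (2 + C)` (Km 2 mM, glycolysis rate-limited below
  ~5 mM), with Vmax 143/103/165 for NX/PX/HX.  The compiled data show no
  usable difference between low- and high-glucose media, so LG and HG
  share constants (overridable).
* **LPR** — by default `ratio * GCR`, with the lactate:glucose ratio
  1.4/1.6/1.8 for NX/PX/HX, times a piecewise-linear pH multiplier
  through (7.4, 1.0), (6.7, 0.75), (6.2, 0.25), clamped to [0.25, 1].
  The anchors encode the measured collapse of lactate production in
  acidic media (~200 to ~150 to ~50 nmol/10^6 cells/h); a continuous
  ramp avoids a discontinuous source term.  Coupling LPR to the
  *instantaneous* GCR captures rate-limited glycolysis; the compiled
  stand-alone LPR Vmax values (207/168/296) differ from `ratio * GCR`
  by at most 3.5% at saturation and are available via
  `lpr_mode = "table"`.

### pH

The original models report pH but not the lactate-to-pH titration they
used.  We adopt the minimal monotone map consistent with all the reported
pH figures: `pH = max(7.4 - slope * lactate, 6.0)`.  The slope is the one
free constant of the package.  It was calibrated once, by solving the
8 x 10^6 cells/ml alginate bead at HX + LG and requiring the day-3
pre-exchange minimum pH to equal 7.0 (the reported value for that
configuration), giving `slope = 0.141` pH/mM, frozen as the default.
Because the map is a documented reconstruction, pH magnitudes elsewhere
are to be read qualitatively (orderings and directions); they are not
quantitative predictions the way the oxygen fields are.

### Proliferation (2D only)

Monolayer populations grow as `N(t) = min(N0 e^{kt}, cap)` with defaults
N0 = 5,000 cells/cm^2, k = 0.348/d (the doubling observed for porcine NP
cells: 28,571 cells/cm^2, i.e. ~80% confluency, after 5 days) and cap
28,571 cells/cm^2.  The culture time is arbitrary in the sense that
results *at a given confluency* are insensitive to k.  3D densities are
held constant: those runs span only ~3 days and the local
microenvironment itself feeds back on division, so constant density is
the honest choice.

## Numerics

The spatial discretization is a conservative finite-volume scheme.
Monolayer vessels reduce to a 1D vertical media column (the solved fields
are laterally uniform to within the reported differences between
vessels), with the monolayer as a time-dependent areal flux at the base.
A single bead, cylinder or pellet in its vessel is meshed axisymmetrically
in r-z with exact cell-volume weighting: cell volumes sum to the liquid
volume exactly (the Eppendorf cone is closed layer-by-layer with exact
frustum volumes), and the construct density is rescaled so the
stair-stepped construct holds exactly the nominal cell number.  The
default resolution places 40 cells across the smallest construct
dimension with geometric grading (factor 1.35) through the media; halving
the spacing moves reported minima by well under 1%.

Time integration is stiff BDF via `deSolve::lsodes` on the sparse
method-of-lines system (relative tolerance 1e-6; absolute 1e-3 uM for
oxygen, 1e-6 mM otherwise).  Sources are evaluated on concentrations
clamped at zero, so they vanish with the substrate and the integration
preserves positivity.  Media exchanges are instantaneous events that
reset media-region cells to fresh values and leave the construct
untouched; the pre-exchange snapshot is defined as exchange time minus
one minute, which is unambiguous at any resolution.  Steady states are
solved directly by damped Newton iteration on the oxygen system
(glucose/lactate at fresh values, residual tolerance 1e-8 of the
boundary scale).  Four auxiliary ODE states integrate consumption,
production and boundary influx so conservation can be checked to
round-off rather than estimated by quadrature.

Multi-bead wells use a reduced-order compartment model rather than a full
3D layout: one representative spherical bead (all beads are identical by
symmetry) exchanges with a 1D media column through the series of its
outer half-shell resistance and the spherical access resistance
`1/(4 pi D R)`, multiplied by N on the media side.  Against the
axisymmetric single-bead model this approximation agrees to well within
1.5 %O2 and 0.3 mM glucose at N = 1, and it preserves the qualitative
contract that depletion and acidification increase strictly with N.

## Scenarios and the randomized generator

`get_scenario()` serves the field's standard configurations.  Quantities
the sources do not print are fixed at documented catalogue or
conventional values, chosen once: well base areas 9.6/3.8/1.9/0.32 cm^2
(6/12/24/96-well), 12-well media volume 2 ml, the Eppendorf as a
truncated cone (bottom radius 1.5 mm, half-angle 8.5 deg, 1 ml fill),
cylindrical constructs centered in a 24-well with 2 ml, and
pellet/microaggregate packing 200 x 10^6 cells/ml (250k cells then form a
sphere of radius ~0.67 mm; 35k, ~0.35 mm), with hydrogel-average
diffusivities inside the pellet.  Feeding is twice-weekly: one exchange
at the midpoint of the 7-day 2D window (day 3.5) and at day 3 for 3D
runs; a daily-refresh schedule can be configured through
`schedule$exchange_days`.

`random_scenario()` draws physically valid scenarios (kind, vessel,
density up to 50 x 10^6 cells/ml, regimes, schedule) deterministically
from a seed; it exists to drive property tests — monotonicity of minima
in density and Vmax, validator coverage — not to emulate any particular
experiment.  What passing those tests shows is that the *solver* behaves
physically across the configuration space; it does not certify the rate
constants for cell types or biomaterials outside the compiled data.

## Problem sizes and verification

The shipped tests and the acceptance script solve each scenario at the
default resolution (meshes of roughly 1,500-2,300 cells; a 7-day
monolayer run takes well under a second, a 3D transient seconds to tens
of seconds).  Verification is layered: exact closed forms (zero-order
sphere `qR^2/6D`, slab `qh^2/2D`, areal-flux column `jL/D`) against
degenerate-parameter scenarios; conservation identities; steady-vs-
transient cross-validation; grid-convergence; and the reported oxygen
minima of the bead, cylinder, pellet and monolayer configurations.

## Limitations

* The lactate-pH map is a calibrated reconstruction (see above); pH and
  glucose figures are ordering-accurate, oxygen is the quantitative
  output.
* No advection, evaporation, meniscus or plate-tilt effects; no
  diffusivity reduction by deposited matrix at high density; no
  metabolic-rate drift with culture time, biomaterial or stimulation; no
  Pasteur-effect switching (the compiled rates do not exhibit one —
  PX has the lowest glycolytic rates).
* Multi-bead wells are a compartment approximation, suitable for
  depletion/acidification questions, not for resolving bead-to-bead
  spatial differences.
* CO2/bicarbonate gas exchange and transport through vessel plastic or
  filter caps are not modeled.
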