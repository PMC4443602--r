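---
title: "Interspecies dust dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspecies dust dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustdose)
```

## The problem

Occupational exposure limits for granular biopersistent dusts (GBS: poorly
soluble, low-toxicity particles such as TiO~2~, carbon black or toner) are
commonly derived by translating rat inhalation studies into a human
equivalent concentration (HEC).  Two translation metrics dominate the
regulatory literature: retained particle **mass per alveolar surface area**
(here *Model A*) and retained particle **volume per alveolar macrophage pool
volume** (*Model B*).  Both sit on the same one-compartment toxicokinetic
core, and both are sensitive to a handful of physiological constants and to
the alveolar deposition fractions produced by the MPPD program.  This
package implements the kinetic core and both translations with explicit
units and provenance, so that every derived limit value can be audited step
by step and its sensitivity to the inputs quantified.

## The one-compartment clearance model

The alveolar region is modelled as a single compartment with a constant
first-order clearance rate $k = \ln 2 / t_{1/2}$:

$$\frac{dB}{dt} = D - kB, \qquad B(0) = 0,$$

where $D$ is the alveolar deposition rate (air concentration $C$ times
alveolar deposition fraction $F_a$ times daily ventilation volume $V_E$;
divided by the particle density $\rho$ when the burden is tracked as a
volume).  The steady state is $B_{ss} = D/k$ and the trajectory is
$B(t) = (D/k)(1 - e^{-kt})$.  Inverting the steady state at a critical
burden $B^\*$ gives the highest air concentration that stays below it:

$$\mathrm{NOAEC} = \frac{B^\* \, \rho \, k}{V_E \, F_a}.$$

Two numerical choices matter and are fixed package-wide:

* **The clearance rate is always $\ln 2 / t_{1/2}$ exactly.**  For the
  60-day rat half-time this is 0.01155/day.  Using the rounded 0.01/day
  sometimes quoted shifts every derived NOAEC by about 15% (0.46 instead of
  0.53 mg/m³ in the reference scenario), so rounding is deferred entirely
  to rendering.
* **Full precision throughout, half-up rounding only at display.**  Rounding
  intermediates propagates visibly: composing the rounded reference cells
  2.66 × 1.52 / 0.58 gives 6.97, while the full-precision computation
  rounds to the published 6.93.  `round_half_up()` implements the rounding
  convention of the published tables (base R's banker's rounding would
  silently flip values like 1.575).

## Units as a first-class object

Every model quantity is a `quantity`: a magnitude with a signed exponent
vector over mass, length and time, and canonical internal base units
mg / m / day.  Unit bookkeeping is not cosmetic here.  One published
derivation chain divides a finished HEC in mg/m³ by a particle density in
g/cm³ and reports the result as a concentration; carried honestly through
the unit layer the result is dimensionless and nine orders of magnitude
smaller:

```{r}
density_division_audit(quantity(1.06, "mg/m^3"), quantity(4.3, "g/cm^3"))
```

`density_division_audit()` deliberately reports both readings — the honest
dimensionless value with its failed concentration-dimension check, and the
unit-dropping magnitude ratio that the published "density correction"
actually computes — because both circulate in the literature.  For the same
reason `combine()` does not refuse dimension-incompatible division: the
invalid value must be carried to a report to make the inconsistency
mechanically visible.  Addition and subtraction, by contrast, hard-fail on
dimension mismatch.  "Breaths" and "cells" are treated as dimensionless
counts; tidal volume × respiratory rate is always folded into a daily
ventilation volume before it reaches the models, so no breath dimension is
needed.

## Model A: mass per alveolar surface

Model A assumes rats and humans respond identically at the same retained
mass per m² of alveolar epithelium.  Equating steady-state burden per
surface across species gives

$$\mathrm{HEC} = \mathrm{NOAEC} \cdot
\frac{F_r V_{E,r} / (k_r S_r)}{F_h V_{E,h} / (k_h S_h)},$$

with absolute (per-animal/per-person) ventilation volumes.  Consequences
that the implementation enforces and tests:

* **Density independence.**  Deposition fractions vary by less than 10%
  across densities 1–5 g/cm³ at a fixed size distribution (and in the
  *increasing* direction), and identical clearance half-times are applied
  to substances of different densities — so the HEC cannot depend on the
  density metadata.  `hec_mass_per_surface()` output is bit-identical under
  density changes, which is asserted in the test suite.
* **Correction factors multiply.**  `corrected_hec()` rescales a reference
  HEC by a revised human/rat surface ratio and a revised human half-time.
  With the reference-method morphometry (143 m² human, 0.41 m² F344 rat,
  ratio 349 versus the cast-derived 193) and the interstitial-sequestration
  half-time (255 versus 400 days), the reference HECs 0.134 and
  1.07 mg/m³ become 0.38 and 3.04 mg/m³.

The rat-side body weight that absolutises the per-kg ventilation defaults
to the scenario rat's own body weight (the 250 g preset in the examples)
and is overridable, since published forward runs do not state their choice;
forward-mode results are therefore documented as this package's own
derivations, not as reproductions of any published forward value.

## Model B: volume per macrophage pool

Model B tracks retained particle *volume* relative to the alveolar
macrophage pool volume.  The classical overload threshold is 6% of the
pool (Morrow's criterion); with $6\times10^7$ macrophages/kg of 1166 µm³
each the rat pool is 70 µl/kg and the threshold 4.2 µl/kg, equivalently
0.93 µl per gram of lung at 4.5 g lung/kg.

The HEC follows from the NOAEC via two adjustment factors:

$$AF_{\mathrm{lungburden}} = \frac{V_{E,r} F_r}{V_{E,h} F_h}, \qquad
AF_{\mathrm{clearance}} = \frac{t_{1/2,h}}{t_{1/2,r}} \cdot
\frac{\mathrm{pool}_r}{\mathrm{pool}_h}, \qquad
\mathrm{HEC} = \mathrm{NOAEC} \cdot
\frac{AF_{\mathrm{lungburden}}}{AF_{\mathrm{clearance}}}.$$

These closed forms are reconstructions: the primary source cites but does
not reprint its factor equations.  They are the unique two-factor
decomposition of the full steady-state burden-per-pool equivalence ratio
$[V_{E,r}F_r/(k_r\,\mathrm{pool}_r)] / [V_{E,h}F_h/(k_h\,\mathrm{pool}_h)]$
that reproduces every published sensitivity-grid cell, and
`hec_volumetric()` recomputes the full ratio on every call and aborts if
the decomposition ever disagrees beyond 1e-10 relative.  Three further
normalisation decisions were genuinely open and are resolved as follows:

* **Everything per kg body weight, on both species.**  The classical
  formula mixes a per-g-lung threshold (1 µl/g) with per-kg-rat
  ventilation (0.29 m³/kg/day).  Restating the threshold per kg raises it
  to 4.2 µl/kg; both threshold readings are first-class scenarios (grid
  rows with 1 and with 4.2 µl/kg) and the ×4.2 factor between them is
  visible in the grid rather than hidden in a unit.
* **Human pool 500 µl/kg body weight.**  The stated human pool
  ($50\times10^{10}$ µm³) is read per kilogram: this is the only reading
  under which the published clearance adjustment factors 0.93 and 0.58
  equal $(t_{1/2,h}/60)\times(70/500)$ exactly.
* **`fvi` defaults to 1.**  The classical NOAEC formula contains a divisor
  `fvi` that its source never defines.  It is carried as an optional
  dimensionless divisor; every published number reproduces with 1, and the
  package makes no further guess about its meaning.

A useful structural property falls out of the algebra and is asserted on
randomized scenarios: the rat deposition fraction cancels between the
NOAEC and $AF_{\mathrm{lungburden}}$, so the HEC depends on the rat side
only through clearance and pool — scenarios differing only in $F_r$ give
identical HECs.

## Deposition fractions are data, not physics

The MPPD deposition model is not reimplemented.  The package ships the
published fractions as keyed rows (program version, species, breathing
pattern, inhalability setting, substance, density) with provenance
strings, because the published record itself shows they are not a smooth
function of the keys: 7.5% / 6.3% / 3.3% for the same rat scenario across
settings and versions, 16.4% vs 8.4% for the human depending on the
breathing-pattern option.  `lookup_deposition()` therefore matches keys
exactly and fails loudly with suggestions — no interpolation.  Fractions
are stored in (0,1); rendering multiplies by 100, avoiding the
percent-vs-fraction confusion that affects the classical formula.  The
settings behind some historical fractions (e.g. the original toner/TiO₂
forward runs) are documented as unrecoverable and are deliberately absent
keys.

## The sensitivity grid

`run_grid()` evaluates the nine bundled scenarios varying program version
and settings (hence $F_r$, $F_h$), the threshold (1 vs 4.2 µl/kg) and the
human half-time (400 vs 250 days), and compares each NOAEC, adjustment
factor and HEC cell against the published reference after half-up rounding
to the printed decimals:

```{r}
g <- run_grid()
g$rows
sum(g$comparison$delta != 0)  # deviating cells out of 36
```

All 36 cells reproduce with zero deviation.  Rendering (`render_grid()`) is
available as CSV and JSON at full precision (render→parse round-trips
exactly) and as markdown at the published decimals.

## The synthetic generator

`sample_scenarios()` draws translation scenarios with uniform ranges
bracketing the published variation: alveolar fractions 3–20% (both
species), rat half-times 30–120 days, human half-times 200–500 days,
densities 1–5 g/cm³, thresholds 0.5–10 µl/kg.  The ranges are deliberately
wide — they are for property testing (decomposition identity, cancellation
invariants), not for representing any particular substance.

`simulate_burden_series()` generates noisy burden time series from the
analytic trajectory with multiplicative lognormal noise (burdens are
positive and errors scale with magnitude; the median observation equals
the trajectory; default sigma 0.05).  `recover_clearance()` fits
$(D, k)$ by least squares on the log scale — matching the multiplicative
error model — with optional bootstrap intervals, and refuses designs whose
time span covers less than one estimated half-time, where $k$ is not
identifiable.  At sigma 0.05 with 20 points over 10–600 days and 500
seeded replicates, the mean recovered clearance rate is biased by well
under 2% — this is the simulation-based acceptance check of the kinetics
core.  What the generator does *not* emulate: overload-dependent
(dose-varying) clearance, interstitial sequestration dynamics (the
two-compartment pathway enters only as a shorter effective human
half-time), inter-animal variability in physiology, or measurement-design
artefacts of real recovery studies — so passing recovery tests demonstrate
correctness of the inverse problem under the model's own assumptions, not
field performance on real lung-burden data.

## Problem sizes and known limitations

All closed-form reproductions are instantaneous; the Monte-Carlo recovery
study uses 500 replicates of 20-point series, a size chosen to estimate a
2% bias bound with comfortable margin while keeping the default test run
fast.  Known limitations: single-compartment kinetics only (no
lymph-node translocation, dissolution or overload kinetics); temperature
and molar units are out of scope for the unit layer; the allometric
scaling for a 330 g rat yields 229.0 days where the literature quotes a
rounded 230; and published forward Model A HECs (0.133/1.02 mg/m³) are
documented as non-reproducible from stated inputs and are treated as
reference constants, never as validation targets.
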