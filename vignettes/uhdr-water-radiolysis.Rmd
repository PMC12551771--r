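---
title: "Simulating water radiolysis at ultra-high dose rates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating water radiolysis at ultra-high dose rates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

FLASH radiotherapy delivers therapeutic doses at ultra-high dose rates
(UHDR, above roughly 40 Gy/s) and spares healthy tissue in ways conventional
dose rates do not. Two candidate radiochemical mechanisms are accessible to
simulation: transient depletion of dissolved oxygen, and *intertrack*
reactions — radicals created by different primary particles meeting while
both populations are still present, which happens only when tracks arrive
close together in space and time. `uhdrchem` simulates both in a
micrometre-scale water target under sequential proton irradiation, scoring
radiation chemical yields (G values, molecules per 100 eV of deposited
energy) and the dissolved-oxygen concentration as functions of time and dose
rate.

The simulated system is a 2×2×2 µm³ cube of neutral-pH water with
reflective walls. Protons (55 MeV, LET 1.169 keV/µm) cross a central
1×1×1 µm³ irradiation volume along z; entry points are uniform on the
1 µm² face; arrival times form a Poisson process over the pulse duration
t_p = D/Ḋ; irradiation stops when the scored dose in the irradiation volume
reaches the target (10 Gy unless configured otherwise). Chemistry is
followed to 1000 s after the first proton.

## Model components

### Physics surrogate (spur model)

Full track-structure transport is out of scope; `generate_track()` replaces
it with a calibrated parametric surrogate. A proton crossing the volume
drops spurs — localized clusters of ionisations/excitations — as a Poisson
process along z with density LET / E_spur (E_spur = 47 eV mean, exponential).
Species are placed at 1 ps around each spur centre with literature initial
yields (per 100 eV: e_aq 4.8, •OH 5.6, H• 0.62, H₂ 0.15, H₃O⁺ 4.8).

Two placement widths matter. Species born at the ionisation core (•OH,
H₃O⁺, H•, H₂) use `spur_sigma_nm` (default 0.9 nm); hydrated electrons
thermalise away from their parent ionisation and use the wider
`electron_sigma_nm` (default 2.2 nm). The pair was calibrated jointly so the
1 µs escape yields land at their standard values, G(e_aq) ≈ 2.5 and
G(•OH) ≈ 2.5 per 100 eV; with a single shared width the electron either
recombines too fast (small σ) or too slowly (large σ) relative to •OH.

Tracks entering near the lateral edge lose the fraction
f(d) = f₀·exp(−d/λ) of each spur's energy and species (d = distance to the
nearest face edge), emulating secondary electrons leaving the irradiation
volume. With f₀ = 1 and λ = 0.0705 µm (solved by
`calibrate_escape_length()`), the mean number of protons needed for 10 Gy
is ≈ 71, against the analytic no-escape count of ≈ 54.

### Chemistry engine

Radiolysis species are point particles performing Brownian motion
(per-axis variance 2DΔt) with mirror-fold reflection at the phantom walls.
Each step applies, in order: diffusion, second-order reactions,
pseudo-first-order scavenging by dissolved O₂, and the oxygen-field update.

Second-order reactions use the Green's-function diffusion-equation (GFDE)
encounter probability for an isolated pair at separation r:
p = 1 for r ≤ R, otherwise p = (R/r)·erfc((r−R)/(2√(D′Δt))), where
D′ is the mutual diffusion coefficient and R the encounter radius derived
from the tabulated rate constant through the Smoluchowski relation
R = k/(4π D′ N_A·10³). All second-order channels are treated as fully
diffusion-controlled at this (reduced) radius. Rate constants follow the
IUPAC convention; for identical reactants (2A → products, d[A]/dt =
−2k[A]²) the radius is derived from 2k so per-pair encounter statistics
reproduce the observed decay law. Candidate partners are searched within
R + 4√(2D′Δt) using a cell list; each candidate reacts by a Bernoulli draw;
a molecule participates in at most one reaction per step (candidates
applied in random order, stale partners skipped). Probabilities are
evaluated at the step-start separation — the erfc expression is the capture
probability within Δt *given* that separation — and survivors then carry
the step's displacement.

The probability is the free-space Green's function: no image terms are
added for the reflective walls. Consequently a population that has diluted
across the phantom reacts more slowly than sealed-box mass action — the
pair sees, per step, only the geometric encounter probability ⟨R/r⟩ once
√(D′Δt) exceeds the box size. This is a deliberate model property, not a
shortcut: a micrometre box re-concentrates radicals artificially, and the
free-space law makes the dilute phase behave like the effectively open
volumes of real irradiation experiments. When steps are fine enough to
resolve the box diffusion time, the same expression integrates exactly to
the mass-action rate 4πRD′Δt/V (∫u·erfc(u)du = 1/4), which the
bimolecular-kinetics oracle test verifies to within 5%.

For performance, a channel whose search radius exceeds `wm_frac`·L
(default half the box edge) is sampled without enumerating pairs: the
free-space probability is averaged over the pair-distance distribution of
uniform points in the cube (precomputed by spherical quadrature), and the
number of reacting pairs is drawn binomially. This is statistically the
same model evaluated cheaply, and it hands over smoothly at the threshold.

Dissolved oxygen is a continuum scavenger: each eligible molecule reacts
with probability 1 − exp(−k·[O₂]·Δt). The concentration starts at
pO₂[%]×760 mmHg×1.26 µM/mmHg (25% → 239.4 µM) and is updated each step
from the recorded generation/consumption counts over the averaging volume
(default the 1 µm³ irradiation volume; configurable to the 8 µm³ phantom).
Species, however, roam and react throughout the whole phantom; only dose
scoring and the oxygen average are tied to the irradiation volume, and all
alive molecules are counted when G values are formed.

### Time stepping

The step ladder resets to 1 ps at every proton arrival (to resolve the
fast intratrack phase) and then grows one decade per decade of elapsed
time, capped at 0.1 s; steps are truncated so they never cross an arrival
or an output time. The ladder is a configurable breakpoint table
(`step_schedule()`).

### Reaction table

The default table (`default_reactions()`) is the standard dilute-water set:
22 reactions among 12 species, including the e_aq/•OH/H• recombination
network, H₃O⁺/OH⁻ neutralisation, and the O₂/HO₂/O₂⁻ family. The two
oxygen scavenging channels are pinned to published values
(H•+O₂ → HO₂•, k = 1.27×10¹⁰; e_aq⁻+O₂ → O₂•⁻, k = 1.48×10¹⁰ M⁻¹s⁻¹).
Elemental (H, O) and charge balance of every entry is audited with water as
the implicit solvent.

Two literature back-reactions, •OH + HO₂• → O₂ + H₂O and
•OH + O₂•⁻ → O₂ + OH⁻, are *excluded* from the default. In this closed
phantom the superoxide pool formed during UHDR irradiation reaches
micromolar levels while •OH is still abundant, and these channels then
return roughly half of the scavenged oxygen: the depletion rate drops to
≈ 0.12 µM/Gy and becomes strongly dose-rate dependent. The model family
this package reproduces is validated against a rate-independent depletion
of ≈ 0.27 µM/Gy ≈ the gross e_aq + H• scavenging yield, which requires the
superoxide pool to be terminal. Users who want the back-reactions can
append two rows to the editable table; doing so roughly halves the net
depletion rate and also roughly halves the UHDR •OH yield at 10 ms
(relative G ≈ 0.15 instead of ≈ 0.3), illustrating how tightly the
oxygen-depletion and hydroxyl-suppression observables are coupled through
this pool.

## Scored observables

* `g_value()` / `scenario_g()`: G = 100·N(t)/E_dep(t), with N counted
  phantom-wide and E_dep the energy scored in the irradiation volume up to
  t. Times are relative to the first proton arrival.
* `relative_g()`: ensemble-mean G at each dose rate normalized to the
  0.02 Gy/s reference at a common evaluation time.
* `o2_depletion_rate()`: OLS slope of end-of-irradiation [O₂] versus dose
  over the 0.5–20 Gy window ("linear interpolation" is read as a linear
  fit), negated; `dose_to_depletion()` extrapolates linearly to zero.
* `ensemble_stats()`: per-scenario G values are computed first and then
  averaged (not pooled), with the unbiased SD.
* Every reaction event carries both reactants' origin-track ids, so the
  intertrack fraction is a first-class output (`intertrack_fraction()`).

## Randomness and reproducibility

One root seed per scenario expands into independent substreams (schedule +
tracks, chemistry) through `derive_seed()`, a counter-based splitting rule
that stays below 2³¹. The compiled kernel draws exclusively from R's RNG,
so identical configuration and seed give bit-identical event logs and
byte-identical CSV/JSON outputs. Ensemble members derive their seeds from
the root seed and the member index.

## Numerical choices and degenerate inputs

* Product placement: the first product of a pairwise reaction appears at
  the √D-weighted point between the reactants (closer to the slower one);
  extra products at the reactant positions. In the mixed regime positions
  are uniform by construction.
* Conflict resolution is random-order with stale-partner skipping; the
  original ordering is immaterial under exchangeability.
* Zero-dose, zero-rate and empty-table inputs error early with the
  offending key named; concentrations clamp at zero (logged through the
  generation/consumption counters).
* The stopping rule uses realized per-track energies, so schedules contain
  a random number of arrivals; removing the last arrival always drops the
  cumulative dose below target.

## What the surrogate does and does not emulate

The spur surrogate reproduces: the LET budget and its spatial clustering
scale, the 1 ps yields, the intratrack recombination that produces the
standard 1 µs escape yields, the edge-escape energy deficit (71 versus 54
tracks), and Poisson statistics per spur. It does not model δ-ray
trajectories, energy-dependent proton slowing, event-by-event ionisation
physics, or LET variation with depth; radial track structure is collapsed
into two Gaussian widths. Tests passing on this surrogate therefore
validate the chemistry engine and the dose-rate phenomenology, not
track-structure physics per se; absolute yields inherit the calibration.

A related caveat: with the default table, the dose-rate suppression of
•OH at 10 ms reaches ≈ 0.3 of the conventional-rate reference at 500 Gy/s,
weaker than the ≈ 0.12 reported by the experimental literature this model
family is compared against. The missing suppression sits in
superoxide-mediated channels whose inclusion would break the oxygen
block (see the reaction-table section); resolving that tension requires
chemistry beyond pairwise diffusion-controlled reactions (e.g. effective
third-order pathways), which is out of scope here.

## Ensemble sizes

The published observables come from 1000-scenario ensembles per dose rate.
The package's tests and the acceptance script use desk-scale reductions
chosen against the quantities' own variability: 500 schedules for the mean
track count, 20–30 scenarios for 1 µs yields, 50–100 for 10 ms hydroxyl
yields, triplicate runs per dose for the depletion fit, and 5–6 scenarios
per rate at the 1000 s horizon. At these sizes every ensemble mean's
standard error is several times smaller than the tolerance of the
corresponding comparison.

## A worked example

```{r, eval = FALSE}
library(uhdrchem)

cfg <- scenario_config(500, pO2_percent = 25, horizon_s = 0.01)
res <- run_scenario(cfg, seed = 1)
res
#> <scenario_result> 69 tracks (40 injected), 37133 eV scored (5.95 Gy), ...

scenario_g(res, "OH", 0.01)        # G(·OH) 10 ms after the first proton
intertrack_fraction(res$events)    # share of pairwise events across tracks
tail(res$o2)                       # spatially averaged [O2] vs time
```
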