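---
title: "Methods: a virtual fruit, its calibration, and ideotype design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual fruit, its calibration, and ideotype design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualfruit)
```

## The model

The package simulates one growing fleshy fruit (tomato is the motivating
system) as two state variables: the mass of water $w$ and the dry mass
$s$, both in grams, from 8 days after anthesis (daa) to ripeness:

$$\frac{dw}{dt} = U_x + U_p + r_w R_f - T_f, \qquad
  \frac{ds}{dt} = U_s - R_f,$$

where $U_x$ and $U_p$ are water inflows from the xylem and phloem, $U_s$
is sugar uptake, $R_f$ respiration, $T_f$ transpiration, and
$r_w = 9/16$ the stoichiometric fraction of respired dry matter returned
as water.  Growth in volume obeys the Lockhart law
$dV/dt = V\,\phi(t)\,(P_f - Y)$ above the yield threshold $Y$, with wall
extensibility $\phi(t) = \phi_{max} e^{-t/\tau_\phi}$.  Equating the
Lockhart rate to the volume change implied by the mass balance yields an
algebraic equation for the turgor pressure $P_f$ at every instant.

Water enters along two pathways, each a pedicel conduit in series with a
composite membrane scaled by the fruit surface area
$A_f = \gamma_A V^{2/3}$:

* xylem — sap treated as pure water, membrane fully reflecting, so the
  driving force is $\psi_{stem} - P_f + \pi_f$;
* phloem — conduit walls impermeable (purely hydrostatic pedicel
  driving), membrane reflecting the fraction
  $\sigma_p(t) = 1 - e^{-\tau_S t^2}$ of the osmotic difference, so the
  driving force is $\psi_{stem} + \pi_p - P_f - \sigma_p(\pi_p - \pi_f)$.

Eliminating the vasculature-node pressure gives the familiar
series-conductance form; a test pins it against an independent two-node
flow-balance root-find.  Osmotic pressures are van 't Hoff values of the
sugar concentration per g water (plus a measured non-sugar term
$\pi_{other}$), with the soluble-sugar fraction of the dry mass linear
in time, $ssrat(t) = a_{ssrat}\,t/24 + b_{ssrat}$.

Sugar arrives by three parallel routes: Michaelis–Menten active uptake
with a logistic decline after $t^\*$ (scale $\tau_A$), solute dragged by
the phloem mass flow (mean concentration $(C_p + C_f)/2$, passage factor
$1-\sigma_p$, zeroed when the phloem flow reverses), and Fickian
diffusion.  Respiration couples to growth,
$R_f = q_g\,ds/dt + q_{m,20}Q_{10}^{(T-20)/10}s$, and the implicit pair
is solved in closed form.

### Numerical treatment

Because every flux is linear in $P_f$ except for the single kink where
the phloem flow changes sign, the turgor balance is piecewise linear and
is solved exactly branch by branch in the compiled core (residuals are
round-off, far below the 1e-8 contract).  An independent R-side
`solve_turgor()` brackets and bisects the same balance; a parity test
holds the two paths together on random states.  Integration is classic
fixed-step RK4 with $dt = 1$ h, a step-halving positivity guard (floor
1/64 h), and flux integrals accumulated with the same RK4 weights, so
the mass budgets close to round-off by construction; a separate check
verifies trapezoid closure of the *reported* hourly fluxes to 0.5%.  A
convergence test against $dt = 0.5$ h justifies the default step.  Stem
water potential follows a half-cosine diurnal course with the predawn
maximum at 05:00 and the midday minimum at 13:00.  Fruit temperature is
taken equal to air temperature.

### Parameters and defaults

Eight genotypic parameters carry the genetic variability
(`phiMax`, `Lp`, `nuM`, `tstar`, `tauA`, `tauS`, `lp1`, `rxp`; xylem
conductivities derive as `lx = rxp*Lp`, `lx1 = rxp*lp1`); three more
(`s0`, `w0`, `bssrat`) open up in ideotype mode.  `table1_bounds()`
holds the admissible boxes.

The non-genotypic constants are fixed defaults, documented as tunable
(`generic_params()`), chosen once so that a genotype at the geometric
centre of the calibration box ripens inside the observed 5–160 g
fresh-mass envelope with a tomato-like dry-matter content:

* `Km = 0.08`, `Cp = 0.14` g g⁻¹ — phloem sap concentration comfortably
  saturating the uptake kinetics;
* `ps = 0.002` — diffusion is a minor route; larger values drive the
  fruit sugar concentration to the phloem value and force unrealistic
  dry-matter contents (20–30%) in small fruit;
* `ap = ax = 0.1` — vascular exchange areas as a tenth of the fruit
  surface;
* `qg = 0.15`, `qm20 = 2.5e-4` h⁻¹, `Q10 = 2` — conventional growth and
  maintenance respiration magnitudes;
* `Y = 1` bar, `tauPhi = 1500` h — yield threshold and slow wall
  stiffening over the 50-day season;
* `Hf = 0.996`, `rhoSurf = 30` cm h⁻¹ — tomato fruit skin is a weak
  transpirer (a peach-like conductance of hundreds of cm h⁻¹ makes
  transpiration consume most of the water influx);
* `piOther = 6` bar — non-sugar osmotica (organic acids, ions) carry a
  substantial share of tomato fruit osmotic pressure; this term also
  rises 1.3-fold under water deficit (measured osmotic adjustment),
  which is what gives some genotypes their deficit resilience;
* `rhoS = 1.6` g cm⁻³, `Msugar = 180` (hexoses),
  `gammaA = (36π)^{1/3}` (sphere).

Active uptake is absolute (g h⁻¹) per the parameter units; a
`dry_mass` scaling variant is exposed as a switch
(`active_uptake_scaling`) but is not the default.

## Calibration

Genotypic parameters are environment independent: the same vector is
simulated under control (C) and water-deficit (WD) inputs, and only the
measured plant inputs differ.  Fit quality is the observation-weighted
NRMSE (percent of the observed mean), one entry per sampled fruit, so
the 15–20 ripe fruits dominate each component.  The four components are
aggregated into $f_1$ (mean of fresh- and dry-mass NRMSE under C) and
$f_2$ (same under WD), minimized jointly by NSGA-II over the calibration
box, with `phiMax`, `Lp`, `nuM` and `lp1` searched in log10 space.  Ten
repeats (reduced budgets in the tests) differ only by seed; archives are
merged, reduced to the non-dominated set, and one solution is chosen by
the min–max rule (smallest worst objective, ties by smaller sum, then
lexicographic parameters).  Failed simulations score a 1e6 penalty
rather than aborting a generation.

With 8 parameters and ~25 fruits per treatment the inverse problem is
under-determined; the package claims trajectory recovery (ripe mass and
dry-matter content within 10% under 5% observation noise), not
identification of the full vector.  A correlation diagnostic across
near-optimal archive members is reported but not gated on.

## Ideotype design

The 11-parameter search maximizes ripe dry-matter content under C
(capped by the constraint $dm_{C,WD} < 10\%$) while minimizing the
fresh-mass loss under WD, inside a size class defined on the control
fresh mass (large 100–300 g, medium 20–80 g, small 5–15 g).  Loss is
reported plainly as $100\,(fw_C - fw_{WD})/fw_C$ by default: the squared
variant printed in some formulations is dimensionally inconsistent with
loss percentages of sensitive genotypes ("lost more than half of its
fresh mass" ≈ 60%), and is kept behind `lossForm = "squared"`.
Solutions with $dm_C \ge 8$ and $loss \le 15$ (inclusive) form the
selected set.

In this stated world the feasible small-class corner is wall-limited:
low `phiMax` caps expansion so the turgor runs high and a −3 bar shift
in stem potential barely moves the growth rate, while a sustained,
moderate active uptake (late `tstar`, long `tauA`) keeps the dry-matter
content in the 8–10% band.  This differs from the high-conductance,
high-uptake mechanism that dominates the large-size class — the
equivalent of which is also visible here (high `nuM` vectors with low
pedicel conductance reach losses of a few percent, but at dm far above
the 10% cap).

## The synthetic population

No accession is deposited with the study, so every downstream stage is
exercised on synthetic recombinant inbred lines: true parameter vectors
drawn log-uniformly (wide parameters) or uniformly inside the
calibration box; a greenhouse-like climate (sinusoidal 18–28 °C, RH
0.5–0.8 in antiphase, optional day-to-day jitter); water deficit
emulated through its measured consequences on the inputs (stem
potentials −3 bar, initial water mass ×0.8, non-sugar osmotica ×1.3,
phloem concentration unchanged); and the study's sampling design (3
fruits in each of the 8–10, 12–15 and 20–25 daa windows, 15–20 fruits
at a fixed per-genotype ripeness age drawn in 45–60 daa).  Observation
noise is multiplicative lognormal with CV 5% (a stand-in; the study
does not state its error magnitude), applied independently to fresh
mass and dry-matter content, with the dry mass re-derived as content ×
fresh mass so it stays below the fresh mass.

What the generator does *not* emulate: genetic linkage between
parameters (draws are independent), a physiological ripening trigger
(ripeness is a sampled date), within-truss fruit position effects, and
the empirical joint distribution of size and dm in the real population
(box-spanning draws produce more extreme dry-matter contents than a
real panel).  A green test therefore establishes that the pipeline
recovers what the simulator generated under the stated design — not
that the biological population looks like this.

## Known limitations

* No cell-division submodel, no plant-level source–sink feedback, no
  fruit energy balance, no elastic volume change.
* The flux functional forms are reconstructions constrained by the
  parameter units and monotonicity descriptions; each sits behind one
  operation so alternatives can be swapped without touching the
  pipeline.
* The min–max choice is applied to the merged archive across repeats
  (a superset of any per-repeat choice, so never worse under the
  criterion).
* PCA/clustering are thin, tested wrappers over `prcomp`/`hclust`
  (complete linkage, first three components by default), with loadings
  scaled to $\sqrt{\lambda_k}$ and a deterministic sign convention.
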