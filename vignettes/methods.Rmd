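---
title: "Methods: simulating and comparing circularity scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing circularity scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrocycle)
```

# The problem this package addresses

How does the degree of crop–livestock integration in an arable rotation
affect the bundle of ecosystem services the rotation delivers — greenhouse-gas
balance, soil-carbon trajectory, nitrate leaching, productivity, and the
stability and resistance of that productivity under a changing climate?
`agrocycle` implements the full comparison chain for three contrasting
8-year circularity scenarios on a temperate-maritime arable region
(Belgian-lowland conditions):

* **BAU** — a cash-crop rotation (sugar beet, potato, maize, cereals,
  rapeseed) whose wheat straw is exchanged off-farm for manure;
* **Vegan** — food crops only, no manure, every crop residue incorporated;
* **ICLS** — an integrated crop–livestock system with 2.5 years of mown
  temporary pasture per cycle; grass and cover-crop biomass feed an on-farm
  sheep flock whose manure returns to the fields.

Winter wheat occupies positions 2 and 4 in all three plans, so wheat seasons
can be compared across scenarios in the very same years.

Running a process-based soil-crop model over thousands of soil clusters is
out of scope here. Instead, the package ships a **seeded synthetic
generator** whose outputs carry the statistical structure the downstream
analysis assumes, so that the whole pipeline — budgets, drought indexing,
resistance statistics, diet optimization, rank tests — is exercised and
tested end-to-end at desk scale.

# The synthetic agroecosystem generator

## Weather

Daily weather (365-day years) is built from a sinusoidal temperature
climatology (annual mean 11&nbsp;°C, half-amplitude 7.5&nbsp;°C) with AR(1)
anomalies, a Bernoulli–gamma precipitation process targeting 837&nbsp;mm/yr,
and Hargreaves–Samani reference evapotranspiration driven by FAO-56
extraterrestrial radiation at 50.5°&nbsp;N. Hargreaves needs only
temperature, which is exactly why it was chosen: the drought index downstream
needs nothing beyond precipitation and PET.

Warming scenarios (+2, +3, +4&nbsp;°C; CO~2~ 475/627/1006&nbsp;ppm) are
*deterministic transforms of the same stochastic draws*: the offset is added
to temperatures, seasonal multipliers dry the summers
(JJA&nbsp;×&nbsp;(1&nbsp;−&nbsp;0.05·ΔT)) and wetten winters and springs
(×&nbsp;(1&nbsp;+&nbsp;0.025·ΔT)), and PET is recomputed from the shifted
temperatures. Scenario contrasts are therefore estimated on matched noise.
Earth-system-model replication is emulated as independent noise streams
(`esm_label`), not as distinct climatologies — the study design uses the
model spread only as replication.

## Crops, nitrogen and carbon

Season outcomes per site × climate × rotation year:

* **Yields** = base yield × warming multiplier × lognormal noise (mean one;
  CV 15% for crops, 10% for grass — pastures are the more stable producer).
  The +4&nbsp;°C multipliers encode the reported per-crop responses
  (sugar beet +70%, maize +19%, potato +21%, rapeseed +28%, wheat +3%,
  pea −1%, faba bean −44%); +2/+3&nbsp;°C values are interpolations, and
  *baseline* yields are plausible regional values, not published ones.
* **Winter-wheat wet penalty**: wheat-year noise is multiplied by
  exp(−k·z&nbsp;−&nbsp;k²/2), where z is the standardized March–May water
  balance of that year, so wet extremes depress wheat while the year-mean is
  left untouched. k defaults to 0.30 (BAU), 0.22 (Vegan), 0.08 (ICLS):
  against the 15% yield CV these magnitudes put the standardized-yield
  depression of a wet-extreme season near −100%, the scale of the pattern
  the generator is built to emulate, with ICLS the least sensitive.
* **Nitrate leaching** is drawn around 4.5&nbsp;kg&nbsp;N/ha/yr × a site
  propensity (lognormal, mean 1) × rotation-and-warming multipliers.
  Historically BAU leaches most (it uses the most fertilizer) and ICLS
  least; under warming the Vegan multipliers grow fastest, overtaking BAU —
  mirroring the reported reversal. The historical multipliers average 1
  across rotations so the pooled historical mean sits at the 4.5 baseline.
* **SOC change** is generated at two depths. Annual topsoil change is
  normal around a rotation mean (BAU −0.23, Vegan −0.10, ICLS −0.02
  Mg&nbsp;C/ha/yr) minus a warming decline; the 0–200&nbsp;cm profile change
  adds a non-negative gamma-distributed subsoil contribution (mineralization
  below 30&nbsp;cm treated as negligible), which enforces
  profile&nbsp;≥&nbsp;topsoil by construction and makes ICLS the only
  profile-positive rotation (+0.30) with Vegan marginally positive (+0.03).
* **Direct N~2~O-N** is drawn per rotation (2.0/1.8/0.9&nbsp;kg&nbsp;N/ha/yr
  for BAU/Vegan/ICLS) with a mild warming increase — the generator hands it
  to the budget as a model output, it is never recomputed from an N balance.

What the generator does **not** emulate: mechanistic soil-water and N
dynamics, spatial covariance between sites, management adaptation to
climate, CO~2~–water interactions at sub-seasonal scale. Passing tests
demonstrate that the *analysis chain* is correct and that configured effect
sizes are recoverable; they say nothing about how a real soil-crop model
would respond.

# Farm-gate GHG budget

Seven signed terms, each a 24-year mean in Mg&nbsp;CO~2~-eq/ha/yr:

1. soil CO~2~ = −(mean ΔSOC~0–200cm~) × 44/12 (sequestration negative; the
   only term allowed below zero);
2. fertilizer-synthesis CO~2~ = 6.17 kg CO~2~-eq per kg N;
3. management CO~2~: 20.5 / 27.6 / 5.6 L fuel per combine / plough /
   surface-tillage pass × 0.81 kg C/L × 3.67 kg CO~2~ per kg C (the printed
   3.67 is used for fuel, the stoichiometric 44/12 for soil — fidelity to
   the printed constants where they are given);
4. direct soil N~2~O (from the generator) × 44/28 × GWP100(N~2~O);
5. indirect N~2~O = 0.75% of leached N + 0.1% of applied N, then × 44/28 ×
   GWP100(N~2~O);
6. CH~4~ (enteric + manure storage + spreading) under GWP100 or GWP*;
7. manure-storage N~2~O (direct + volatilization-indirect), ICLS only —
   for BAU, with the animals off-farm, only spreading CH~4~ crosses the
   farm gate.

GWP100 defaults are AR6 (CH~4~ 27.2, N~2~O 273). Livestock and manure
coefficients are IPCC Tier-1 style defaults (feed conversion 6 kg DM per kg
live-weight gain, dressing 48%, retail fraction 75%, CH~4~ yield 21.9 g/kg
DMI, B0 0.19 m³/kg VS, storage MCF 2%, spreading 1%, EF~direct~ 0.005,
volatilized fraction 12%, EF~indirect~ 1%) — all configurable and none of
them taken from the study being emulated.

**GWP\***. The warming-equivalent series is
E\*~(t)~ = GWP100 × [ (rH/Δt)(E(t)&nbsp;−&nbsp;E(t−Δt)) + s·E(t) ] with
r = 0.75, s = 0.25, H = 100, Δt = 20: a constant series maps to
0.25·GWP100·E, a fresh pulse to 4·GWP100·E. Years before the simulation
assume the year-1 rate (stable herd). Two consequences worth stating
plainly:

* `gwp_star_series()` is the literal per-series operation and is tested
  against those closed forms;
* in `assemble_budget()` the conversion is applied to the **farm-level
  emission rate** — the rotation-cycle average of the simulated per-field
  series — because every rotation phase is present on the farm in every
  year. Applying a rate-change metric to one field's phase sequence would
  manufacture spurious CH~4~ "pulses" out of the rotation's internal
  structure.

# SPEI-3 and event classification

The monthly water balance D = P − PET is summed over rolling 3-month
windows and standardized per calendar month through a three-parameter
log-logistic distribution fitted by unbiased probability-weighted moments,
then mapped through the standard normal quantile function. The fit uses the
generalized-logistic parameterization (shape k = −τ~3~), which is the same
family extended to both skew directions: an aggregated synthetic balance can
be nearly symmetric or left-skewed, where the textbook right-skew-only
formulas degenerate; k&nbsp;<&nbsp;0 reproduces the classical log-logistic
exactly. Values outside the fitted support saturate at the corresponding
tail, and probabilities are clamped to [10⁻⁷, 1−10⁻⁷] before the normal
quantile map.

Calibration requires ≥ 20 years and is done **once, on the
historical-analogue window**; future scenarios are standardized with the
frozen coefficients and classified against the frozen thresholds, so future
events are judged against today's climate (no recalibration leakage — a
property the suite tests directly).

Each wheat season is labelled by the SPEI-3 value dated May (the March–May
window before flowering) against the historical per-site quantiles:
below q~0.10~ extreme dry, q~0.10~–q~0.25~ moderately dry, q~0.25~–q~0.75~
normal, q~0.75~–q~0.90~ moderately wet, above q~0.90~ extreme wet.
Quantiles use linear interpolation (type 7), and a value falling exactly on
a threshold goes to the more extreme class — "once per decade" phrasing
excludes the boundary from normal.

# Productivity, stability, resistance, normalization

* **Productivity** per 8-year cycle in three metrics: mass (Mg/ha; roots
  and tubers fresh-equivalent), energy (cereal units from per-crop
  coefficients), and economic value (price × yield − fixed costs). ICLS adds
  sheep live-weight gain (mass), its cereal-unit equivalent, and retail meat
  value. The value tables ship as editable configuration with placeholder
  regional values.
* **Stability** = μ/σ of the per-cycle totals, with the sample (n−1)
  standard deviation — three cycles per 24-year run is a small n. σ = 0 is
  flagged undefined and excluded from aggregation rather than mapped to
  infinity. Whether σ should be taken across the three cycle totals or the
  24 annual totals is genuinely ambiguous; the package reads "productivity
  of a single rotation" as the cycle total and exposes the annual
  alternative through `productivity(per = "year")`.
* **Wheat standardization**: z-scores × 100 within site × climate scenario,
  *pooling the three rotations*. The rotations' wheat crops grow in the same
  years, and only a shared yardstick makes their event responses comparable
  — a rotation whose wheat shrugs off a wet extreme then genuinely shows a
  smaller standardized deviation. Between-class differences can exceed 100
  in magnitude by construction.
* **Resistance** Ω = 1/|Y~e~ − Ȳ~n~|: the reciprocal deviation of an event
  season's standardized yield from the mean over normal-labelled seasons of
  the same site, scenario and rotation. Deviations under ε (default 10⁻⁶)
  are capped at 1/ε and flagged — downstream medians and rank tests need
  finite values. Group summaries are medians after 1.5×IQR outlier removal.
  The variant Ω₂ = Ȳ~n~/|Y~e~ − Ȳ~n~|, which folds the normal-year level
  into the index, is available behind `use_omega2` and off by default.
  Sites where a warmed scenario leaves no normal-labelled wheat season carry
  no reference and are excluded by the pipeline.
* **Multi-criteria normalization**: each criterion is indexed to the BAU
  value (BAU = 100). When BAU is negative while other rotations are positive
  — the profile-SOC case — the index divides by |value~BAU~| so BAU sits at
  −100 and sequestration keeps its sign. The rule is idempotent.

# Diet supply–demand optimization

Crop products and by-products map to commodity energy supplies
(kcal/ha/yr); ICLS adds retail meat. Fruits, vegetables and tree nuts are
produced outside the rotation and enter only as a fixed energy contribution
on the demand side. The optimizer is a **pure seeded random search**, the
simplest faithful reading of "sample priors, evaluate, keep the best":
per-commodity daily intakes are drawn within reference-diet bounds (vegan
mode zeroes the animal commodities), people-fed-per-hectare within its
prior, animal intakes induce feed demand through feed-conversion factors,
and the objective is

> 10 × |energy − target|/target + 1 × Σ(deficit + surplus)/Σsupply,

the energy gap carrying the larger weight. The exact prior shapes and the
weight ratio are not documented in the source material; uniform priors and
10:1 are this package's choices, configurable under `diet:`. The incumbent
best never worsens with iterations (tested), and the returned balance
satisfies supply + deficit − surplus = demand with deficit·surplus = 0 per
commodity.

# Scenario comparison statistics

Rank-based throughout (the simulated indicators are far from normal):
Kruskal–Wallis across rotations, then Dunn's pairwise z statistics on the
joint ranking with tie correction, summarised as compact letters
(insert-and-absorb). Values are subsampled at 1/100 by default, with the
*same* record indices in every group when group sizes match — emulating
paired site subsampling. No multiplicity adjustment is applied beyond the
test's construction unless configured (`stats$p_adjust`), and the p
threshold defaults to 0.05. Outliers use the 1.5×IQR rule with type-7
quartiles; with IQR = 0 the closed interval flags nothing.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives an independent stream from the user
  seed plus string labels (site, module, rotation, noise-stream label) via a
  small multiplicative hash kept within 32-bit range; climate scenarios
  deliberately share streams so warming is a paired transform.
* Zero-variance yield groups, σ = 0 stability, |Y~e~−Ȳ~n~| ≈ 0, and
  constant water-balance months are flagged or rejected explicitly rather
  than propagated as infinities.
* The no-leap 365-day calendar keeps month arithmetic exact; dates are
  cosmetic labels.

# Problem sizes

The shipped tests run the generator at 1–60 sites for construction checks
and at 200 sites × 24 years × {historical, +4 °C} × 3 rotations for
parameter recovery and the ordering checks; `scripts/acceptance.R` uses the
same 200-site setting. These sizes put Monte-Carlo error comfortably inside
the asserted bands (the leaching mean, for instance, carries a standard
error of ~2% at 200 sites) while a full run stays in the minutes range on a
single CPU.

# Known limitations

* All absolute levels downstream of the generator inherit its placeholder
  baselines (yields, prices, cereal units, diet tables); only the encoded
  relative effects and the budget constants are anchored to reported values.
* The livestock module is a static Tier-1 conversion — no herd demography,
  no grazing, no feed-quality dynamics.
* The diet optimizer explores a box prior by pure random search; with many
  commodities the returned optimum is an approximation whose quality grows
  slowly in `n_iter`.
* Sites are statistically independent; regional aggregates therefore
  understate the spatial autocorrelation a real landscape would show.
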