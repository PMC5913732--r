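---
title: "Evaluating rootable depth and root zone water capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating rootable depth and root zone water capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rzpawhc)
```

## The problem

How much plant-available water a soil offers a maize crop depends on three
things at once: how much water the fine earth holds between field capacity
and wilting point (PAWHC), how much of the soil volume is fine earth at all
(SFEF), and how deep roots can actually go (RZD). Each varies with depth, and
the binding constraint is often not the water retention but the rootable
depth — a sodic subsoil, a gravel bed, a shallow water table. This package
evaluates all three components per depth interval from routinely measured
soil properties and aggregates them into a single root zone plant-available
water holding capacity in mm.

Inputs are tidy layer tables — one row per profile × depth interval, columns
as in `profile_columns()` — or, equivalently, directories of per-property
per-interval ASCII grids. The six standard reporting intervals (0–5, 5–15,
15–30, 30–60, 60–100, 100–200 cm) are the default the synthetic generator
emits, but any ordered, contiguous-from-0 set of intervals is accepted.

## Water retention and the pedotransfer function

Retention per layer follows the van Genuchten curve
$\theta(h) = \theta_r + (\theta_s - \theta_r)\,[1 + (\alpha h)^n]^{-(1-1/n)}$
with parameters predicted by a regression developed for tropical soils from
sand, silt and clay (g/100 g), organic carbon (g/kg, converted to %), bulk
density of the fine earth (kg/dm³), CEC (cmolc/kg) and pH-H₂O. CEC and pH
act as proxies for the low-activity-clay mineralogy of highly leached
soils — two layers with identical texture but different CEC/pH get different
curves. The coefficients ship as a plain-text file
(`inst/extdata/ptf_tropical_vg.csv`) with their provenance and unit
conventions in the header, and `rz_config(ptf_coefficients = ...)` swaps in
alternatives, so the PTF is pluggable and auditable.

Three conventions matter and are deliberate:

* Suction heads use the stated equivalences pF 2.0/2.3/2.5 → 100/200/300 cm
  and pF 4.2 → 15,000 cm, not `10^pF`. The PTF's `alpha` is fitted in 1/kPa
  and converted with 1 kPa = 10.19716 cm of water.
* Field capacity defaults to pF 2.3 for every texture
  (`rz_config(fc_pf = )` switches to 2.0 or 2.5). A texture-dependent FC is
  intentionally not implemented: with texture varying across depth and
  space it yields inconsistent 3-D results.
* A regression can return a slightly negative residual moisture θr; it is
  clamped to 0 with a warning (and θr is kept strictly below θs), preserving
  the parameter invariants on degenerate inputs.

PAWHC is `vmc_fc − vmc_pwp` in v%. If a table already carries `vmc_sat`,
`vmc_fc`, `vmc_pwp` (measured retention) or fitted `theta_*`, `alpha`, `n`
columns, those are used as given and the PTF is bypassed.

## Rootability rules

Each of 14 soil factors is scored per layer by a rootability index (RI,
0–100% adequacy for root growth) that is piecewise-linear in one soil
property, constant beyond its outer breakpoints, with the breakpoint table
shipped as `inst/extdata/rootability_rules.csv` (overridable via
`rz_config(rules = )`, which makes threshold-sensitivity experiments a
one-flag rerun). Four derived variables feed the rules: saturated moisture
content as the porosity proxy; `f_bd = bd − (1.6 − 0.0035·clay)`, bulk
density in excess of a texture-dependent critical density (1.60 kg/dm³ for
pure sand, 1.25 for pure clay); the interval-to-interval increases of sand
and clay content, assigned to the deeper interval, as the abrupt-texture-
change proxies; and the aluminium saturation `100·exch_al/cec`.

A layer is adequate if and only if every evaluated factor has RI ≥ the
threshold index (20% by default); restriction requires RI strictly below
it. Factors whose input property is missing are skipped with a log message,
never treated as adverse — the framework stays runnable on incomplete
profile databases, which routinely lack carbonate, gypsum or EC data.

The per-interval indices are made depth-continuous by linear interpolation
through the interval midpoints (2.5, 10, 22.5, 45, 80, 150 cm for the
standard intervals), constant above the first and below the last midpoint.
The interpolation scheme is a design choice: linear is the only option
consistent with the rules themselves being piecewise linear, and unlike a
cubic spline it cannot overshoot below 0 or above 100. A brute-force 1 cm
scan of the interpolated profile guards the analytic crossing computation in
the test suite. The restriction depth of a factor is the shallowest depth
where its continuous RI drops below the threshold; at the crossing itself
(RI exactly 20%) soil still counts as adequate, so the reported depth is the
infimum of the restricted zone. Two clauses of the texture-change rule —
its nominal validity "over an assumed minimal distance of 15 cm" — are
documented but not enforced: the consecutive-interval difference is the only
operational definition available, and interval thicknesses are what they
are.

## Profile-level depth limits and the RZD decision

Two limits apply to the profile as a whole. The depth of aerated soil is
interpreted from the ordinal drainage class (1 very poorly drained … 7
excessively drained) through the quadratic `2.5x² + 22.5x − 15`, giving 10,
40, 75, 115, 160, 210, 265 cm; classes 5–7 exceed the 150 cm crop maximum
and therefore never limit. Depth to bedrock is the shallower of the recorded
value and the top of the first layer with coarse fragments above 90 v%.

RZD is the minimum of the layer-factor restriction depths, bedrock,
aeration, and the 150 cm genetic maximum of maize. Missing drainage class or
bedrock information makes that candidate non-limiting (a censored depth is a
minimum soil depth, not evidence of shallowness). Tie-breaking among equal
candidates is not defined by the framework itself, so the package fixes a
deterministic precedence — crop maximum, then bedrock, then aeration, then
layer factors in rule-file order — which keeps single-factor attribution
reproducible; the summary (`summarize_limiting_factors()`) reports extent
(km²), degree (cm) and severity (restricted volume, km³, as
area × (150 − RZD) × 10⁻⁵) per limiting factor, and the factor volumes sum
to the total restricted volume by construction.

## Aggregation

Each interval contributes `overlap(interval, [0, RZD]) × PAWHC/10 × SFEF`
mm; 1 cm of soil at 1 v% holds 0.1 mm of water, which makes a 10 v%,
coarse-fragment-free, unrestricted soil hold exactly 150 mm over 150 cm.
Intervals cut by RZD (aeration depths, for instance, fall mid-interval)
contribute pro rata — restriction depths are continuous, so no snapping to
interval boundaries occurs — and the 100–200 cm interval contributes at most
its overlap with the crop depth. Alongside the absolute capacity the result
carries the thickness-weighted mean PAWHC and SFEF over the root zone and a
nested decomposition (capacity at the 10 v% reference with no limits; with
actual PAWHC; additionally with SFEF; additionally truncated at RZD). The
reference member uses 10 v% by definition, so actual-PAWHC capacity may
exceed it; the later members are provably nested.

## The synthetic generator

`generate_profiles()` emulates the statistical shape of a continental
legacy-profile compilation: property marginals inside the observed min–max
ranges, the heavily skewed properties (coarse fragments, EC, exchangeable
Na) drawn log-normal, clay mildly increasing and organic carbon decreasing
with depth. Benign baseline profiles are constructed to be adequate on every
factor (bulk density below the critical density, pH 4.8–7.5, salts low,
drainage classes 5–7), and scenarios inject documented adverse conditions
into the subsoil — e.g. `sodic_lowland` raises exchangeable Na above its
4.2 cmolc/kg threshold below 30 cm. The `mixed` scenario cycles
deterministically through 17 targeted injections so that, at n ≥ 17, every
rootability factor and every profile-level limit occurs as the attributed
limiting factor; the targeting must respect the physics (a saturated
moisture content low enough to restrict porosity forces bulk density past
its own critical value too, so that pair is separated by the attribution
precedence, and the aluminium-saturation case uses a low-CEC soil whose
absolute aluminium stays adequate).

One `set.seed(seed)` governs a generation run; profiles draw sequentially
from that stream and the caller's RNG state is restored afterwards. What the
generator does *not* emulate: spatial correlation between cells of a raster
fixture, measurement error, censored or missing observations, and the
narrow smoothed property ranges of interpolated maps. Tests passing on
these fixtures therefore demonstrate the correctness of the evaluation
logic, not the accuracy of any map product.

## Numerical and design choices

* Depths are cm, intervals half-open `[top, bottom)`, contiguous from 0;
  non-standard intervals are accepted everywhere.
* Evaluation proceeds to `max_crop_depth` (150 cm default) even though the
  deepest standard interval reaches 200 cm; the 100–200 cm layer simply
  contributes its 50 cm overlap.
* `f_bd` at exactly 0 maps to RI 100 (continuity of the rule's flat
  segment); alkalinity and acidity are both always evaluated — their
  breakpoints cannot both be below threshold at once.
* Aluminium saturation with CEC ≤ 0 is undefined: the factor is skipped
  with a warning rather than divided by zero, and saturation is capped at
  100%.
* Rasters are plain-text ESRI ASCII grids with a declared nodata value;
  nodata becomes "missing", never 0, and a cell missing any required
  property is set aside and flagged rather than evaluated. Grids must share
  registration exactly; no resampling or reprojection is attempted.
* An RZD of 0 yields a valid 0 mm capacity, not an error.

Problem sizes in the test suite — 1,000 mixed profiles for the
restriction-depth scan, ~1,000 layers for the retention monotonicity sweep,
5 × 5 fixture grids for path equivalence — were chosen as the smallest sets
that exercise every rule, every limiting factor and every crossing geometry.

## Known limitations

The PTF is a regression: outside its tropical calibration domain (e.g.
andic or organic soils) its parameters are extrapolations, and it tends to
overestimate retention at high tensions, so PAWHC is conservative. Rule
breakpoints encode maize requirements; other crops need a different rules
file and maximum depth. The framework does not model soil moisture
dynamics, capillary rise from groundwater, or management-alterable
restrictions (pans that can be ripped, penetration resistance), and the
morphology and oxide-induration factors have no operational
parameterisation and are not evaluated.
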