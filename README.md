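# rzpawhc

Rootable depth and root zone plant-available water holding capacity of soil
profiles, for maize.

In rainfed cropping, the water a soil can hold within the depth that roots
can actually reach — the root zone plant-available water holding capacity,
RZ-PAWHC — governs how a crop rides out dry spells and how it responds to
seeds and fertiliser. `rzpawhc` implements the evaluation framework that
turns routine per-depth-interval soil properties (texture, organic carbon,
bulk density, CEC, pH, coarse fragments, salts) into that single capacity in
mm, for agronomists, land evaluators and soil modellers working with profile
databases or gridded soil property stacks.

## The model

RZ-PAWHC decomposes into three components, each computed per standard depth
interval (0–5, 5–15, 15–30, 30–60, 60–100, 100–200 cm):

1. **PAWHC of the fine earth** (v%): the difference between volumetric
   moisture content at field capacity (pF 2.3 by default, i.e. 200 cm
   suction) and at permanent wilting point (pF 4.2, 15,000 cm), read off a
   van Genuchten retention curve
   θ(h) = θr + (θs − θr) / [1 + (αh)ⁿ]^(1−1/n)
   whose parameters come from a pedotransfer regression for tropical soils
   on sand, silt, clay, organic carbon, bulk density, CEC and pH-H₂O.
2. **Soil fine earth fraction** (SFEF): coarse fragments (v%) deducted from
   100% — the volume roots can exploit.
3. **Root zone depth** (RZD, cm): the shallowest of (a) the depth where any
   of 14 piecewise-linear rootability-index rules (porosity, soil volume,
   texture, induration, acidity, alkalinity, salinity, sodicity, aluminium
   toxicity) falls below the 20% threshold index, (b) depth to bedrock
   (recorded, or a layer with > 90 v% coarse fragments), (c) the depth of
   aerated soil implied by the drainage class (2.5x² + 22.5x − 15 cm for
   class x = 1…7), and (d) the genetic maximum rooting depth of maize,
   150 cm.

Finally RZ-PAWHC = Σ over intervals of overlap(interval, [0, RZD]) ×
PAWHC/10 × SFEF, in mm; a soil with 10 v% PAWHC, no coarse fragments and no
restriction holds exactly 150 mm.

## Worked example

```r
library(rzpawhc)
profiles <- generate_profiles("mixed", n = 6, seed = 42)
ev <- evaluate_profiles(profiles, quiet = TRUE)
tidy(ev)[1:6]
#> # A tibble: 6 × 6
#>   profile_id   rzd limiting_factor  rz_pawhc_mm pawhc_weighted_v sfef_weighted
#>   <chr>      <dbl> <chr>                  <dbl>            <dbl>         <dbl>
#> 1 mixed_0001  40.5 porosity_vmc_sat        28.5             7.11         0.990
#> 2 mixed_0002  40.5 porosity_f_bd           35.2             8.91         0.964
#> 3 mixed_0003  43.2 volume_crsvol           33.5            10.9          0.709
#> 4 mixed_0004  43.1 texture_sand            33.6             7.99         0.976
#> 5 mixed_0005  41.8 texture_f_sand          44.0            10.9          0.972
#> 6 mixed_0006  42.6 texture_f_clay          40.8            10.0          0.948
```

Each row is one profile: `rzd` is the rootable depth in cm,
`limiting_factor` names the restriction that set it (here each synthetic
profile was built to trip a different rule in its subsoil below 30 cm, so
every rootable depth lands a little above 40 cm — the linear crossing
between the 22.5 cm and 45 cm interval midpoints), `rz_pawhc_mm` is the
water capacity within that depth, and the last two columns are the
thickness-weighted mean PAWHC (v%) and fine earth fraction over the root
zone. `glance(ev)` condenses the run (here: mean RZD 42.0 cm, mean RZ-PAWHC
35.9 mm) and `summarize_limiting_factors(ev$depth_eval)` tabulates extent,
mean restricted depth and restricted soil volume per limiting factor.
`autoplot(ev, type = "depth")` draws the per-profile depth chart.

Gridded input works the same way: `evaluate_raster_stack(dir)` evaluates a
directory of per-property, per-interval ASCII grids cell by cell, and
`generate_raster_fixture()` writes a synthetic stack for testing. A thin
command-line front end is installed at `inst/cli/rzdeval.R`
(`evaluate` / `generate` subcommands).

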