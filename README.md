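# burrowscape

Spatial avoidance analysis for two burrowing mammals — a colonial ground
squirrel (the spotted souslik, *Spermophilus suslicus*) and the European
mole (*Talpa europaea*) — from zone-based presence/absence plot surveys and
remotely sensed molehill maps.

The package is written for spatial ecologists and conservation
practitioners who need to (a) test whether two burrowing species co-occur
at random or avoid each other, (b) turn a map of mole mounds into an
"occupied area" estimate and a habitat/monitoring-effort account, and (c)
evaluate automated mound detection on aerial imagery. Because real field
data of this kind are rarely released, the package also ships a synthetic
landscape generator with a *known, tunable avoidance parameter*, so the
whole pipeline is testable end to end and its statistical operating
characteristics (type-I error, power, parameter recovery) can be measured.

## What it computes

**Survey zones.** Around each inhabited nest burrow a circular plot of
area $A = 10\,\mathrm{m^2}$ (radius $r = \sqrt{A/\pi} = 1.78$ m, diameter
3.56 m) is scored 1/0 for mole-mound presence (zone BURROW). The colony
(zone COLONY) is the 95% kernel-density isopleth of the burrow locations
minus a 4 m exclusion disc around every burrow; the rest of the grassland
is CONTROL. Random plots in COLONY and CONTROL keep centres at least 8 m
apart.

**Occupied area.** For a point set $\{x_i\}$ the density surface is a
fixed-radius uniform-disc kernel: each point spreads unit mass over the
disc of radius $h$ (5 or 10 m for the mole area). The occupied area is the
smallest set of highest-density grid cells holding 95% of the total mass,
with all cells tied at the threshold density included.

**Avoidance statistics.** Presence is modelled by logistic regression on
the zone factor,
$\mathrm{logit}\,P(Y=1) = \beta_0 + \beta_{\mathrm{COLONY}} + \beta_{\mathrm{CONTROL}}$
(reference BURROW). The model is evaluated with the AUC (Mann–Whitney rank
statistic, ties at half credit), and zones are compared pairwise with
unadjusted (LSD-style) Wald contrasts on the log-odds scale; completely
separated zones fall back to Fisher's exact test.

**Detection evaluation.** Boxes match greedily in score order at
IoU > 0.5; duplicate detections of one truth are false positives;
precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$,
$F_1 = 2TP/(2TP+FP+FN)$, and AP is the all-point interpolated area under
the precision–recall curve. A classical blob detector (threshold +
connected components + 15–50 cm size prior) provides a trained-model-free
baseline on synthetic imagery.

**Habitat and effort.** Remaining habitat = total − mole area; an observer
at 3 km/h inspecting a 5 m strip needs 2 km and 40 min per hectare, and
10 ha is one person-day — so excluding a 40 ha mole area saves ~27 h, an
80 km route, and 4 person-days per survey.

## Worked example

One simulated survey year under the calibrated 105 ha preset (228 burrows,
200 BURROW / 100 COLONY / 120 CONTROL plots):

```r
library(burrowscape)

cfg <- preset_paper2019(master_seed = 1)
y   <- run_year(cfg, 2)   # the 2019-like year
y$freq
#> # A tibble: 3 × 5
#>   zone     year n_plots n_present proportion
#>   <chr>   <int>   <int>     <int>      <dbl>
#> 1 BURROW   2019     200        18       0.09
#> 2 COLONY   2019     100        13       0.13
#> 3 CONTROL  2019     120        48       0.4

pairwise_lsd(y$fit)
#> # A tibble: 3 × 6
#>   zone_a zone_b  diff_log_odds     z  p_value method
#>   <chr>  <chr>           <dbl> <dbl>    <dbl> <chr>
#> 1 BURROW COLONY          0.413  1.07 2.86e- 1 wald
#> 2 BURROW CONTROL         1.91   6.17 7.01e-10 wald
#> 3 COLONY CONTROL         1.50   4.26 2.03e- 5 wald
```

Mole mounds are scarce at burrows (9%), intermediate in the colony (13%)
and common outside it (40%); the BURROW–CONTROL contrast is significant at
p = 7e-10 — the spatial-avoidance signature the package is built to
detect. The model summary and the monitoring arithmetic:

```r
glance(y$fit)
#> # A tibble: 1 × 6
#>       n   auc deviance null.deviance df.residual any_separation
#>   <int> <dbl>    <dbl>         <dbl>       <int> <lgl>
#> 1   420 0.713     360.          406.         417 FALSE

effort_report(40)
#> # A tibble: 1 × 7
#>   area_ha minutes_per_ha route_km_per_ha total_minutes total_hours ...
#> 1      40             40               2          1600        26.7 ...
```

`run_scenario(cfg, out_dir)` chains all stages — pattern generation,
zones, plot scoring, zone models, occupied-area/habitat accounts, imagery
rendering and blob-detection evaluation — and writes CSV/JSON outputs plus
a reproducibility manifest. `autoplot()` methods display frequency tables,
density grids, regions and orthoimages; `plot_patterns()` maps the two
species.

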