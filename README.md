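# reefrestore

Can coral restoration be scaled up, and is it being put where it helps?
`reefrestore` implements a global audit of coral-reef restoration as a
reusable, fully tested R pipeline, aimed at conservation ecologists and
spatial modellers. It answers four questions on a 0.5° reef-locality grid:

1. **Where does restoration happen?** A boosted-regression-tree (BRT)
   classifier separates restored from non-restored localities using
   accessibility (gravity, remoteness), cumulative human impact, coral
   richness and pre-restoration bleaching-alert exposure. Spatial
   autocorrelation is controlled by greedy thinning (>150 km haversine
   separation) with a join-count randomness screen; class imbalance by
   inverse-prevalence weights; skill is the true skill statistic
   (TSS = sensitivity + specificity − 1) maximised over thresholds
   0.001–0.900.
2. **Is short-term success predictable?** Success is standardized against
   an expected-survival decay curve S_e(t) = a + (100 − a)e^(−kt):

       S_r = log_e(1 + 100 − ((S_e − S_o)/S_e)·100) = log_e(1 + 100·S_o/S_e)

   so S_r = 0 at total mortality and log_e(101) ≈ 4.615 when observed
   survival S_o matches the expectation. A BRT regression of S_r on
   technique, environment and exposure predictors is cross-validated on
   1 km-deduplicated, Moran-screened record sets; when mean test R² < 0.05
   the variable-importance report is suppressed as misleading.
3. **What thermal stress do restored sites face?** Yearly fractions of
   recently restored (past 5 years) versus control localities exposed to
   NOAA bleaching alerts (level I: heat stress > 1 °C with DHW 4–8
   °C-weeks; level II: DHW ≥ 8), and counts and first years of projected
   annual-maximum DHW ≥ 20 °C-weeks (a mass-mortality proxy) over
   2015–2100.
4. **What would scaling up cost?** Linear per-hectare extrapolation under
   per-technique low/median/high cost bounds, e.g. restoring 10% of the
   11,700 km² of recently degraded reef (117,000 ha) costs ≈ US$16.7
   trillion at the US$143M/ha upper bound and ≈ US$3.3 billion at the
   coral-gardening median.

A synthetic-data module generates reef grids, restoration records, alert
histories and DHW projections with known planted structure (logistic
covariate effects, a Gaussian random field clustering restored sites,
log-normal survival noise), so the entire pipeline runs and is testable
with no external download.

## Worked example

```r
library(reefrestore)

g <- generate_grid(sim_config(
  n_localities = 1200, restored_fraction = 0.12,
  beta = c(gravity = 2, remoteness = -1.2, impact_mean = 0.5,
           impact_trend = 0, coral_richness = -0.3),
  spatial_range_km = 250, spatial_sd = 0.6, seed = 11))
g
#> Synthetic reef grid: 1200 localities, 136 restored
#>   alert years 1986 - 2021 ; DHW years 2015 - 2100

fast <- brt_config(learning_rate = 0.05, bag_fraction = 0.5,
                   tree_complexity = 3, tree_range = c(50, 300),
                   tree_step = 10, n_folds = 3)
run_site_selection(g, config = site_config(replicates = 6, brt = fast),
                   seed = 5)
#> Restoration site-selection model (6 replicates)
#>   TSS  = 0.58 +/- 0.12
#>   FPR  = 0.17 +/- 0.08 ; FNR = 0.25 +/- 0.15
#>   Relative influence (%):
#>     gravity           50.3
#>     remoteness        28.2
#>     impact_mean       10.1
#>     ...
```

The planted accessibility effects (restoration probability rising with
gravity, falling with remoteness) are recovered: gravity ranks first in
relative influence, the classifier clearly beats chance (TSS 0.58 against
0 for a chance-level model), and both error rates stay moderate. With
`beta` all zero the same run returns TSS ≈ 0.

```r
ex <- dhw_exceedance(g)
ex$groups
#>      group    n fraction_exceeding events_mean first_year_mean
#> 1 restored  136             0.9044       28.72            2066
#> 2  control 1064             0.8797       24.36            2069
```

Under the default warming trend (0.30 ± 0.10 °C-weeks yr⁻¹) ~90% of
restored localities see at least one mass-mortality-level year before
2100, first around the mid-2060s — slightly worse than control sites, as
configured.

```r
cost_curve(default_cost_table(), area_for_fraction(11700, 0.10))
#>                      technique area_ha ...   median_usd   high_usd
#> 1              coral_gardening  117000 ...   3299985000 2.1060e+11
#> 3              artificial_reef  117000 ... 140400000000 1.6731e+13
```

`run_all(pipeline_config(...))` chains every stage (simulate →
collinearity screen → site selection → success model → exposure → future
DHW → costs) under one seed and can write a JSON/CSV report bundle.

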