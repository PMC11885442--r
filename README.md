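# whalemigrate

Satellite-telemetry track processing and breeding-migration phenology for
deep-diving whales.

Adult male sperm whales feed at high latitudes and travel thousands of
kilometres to low-latitude breeding grounds, but the timing, duration and
routes of these migrations are hard to measure: the only practical data
source is Argos satellite tags, which deliver irregular, noisy, gappy
position streams and coarsely binned dive summaries. This package is for
movement ecologists working with such data. It implements the full chain
from raw Doppler fixes to a per-animal migration calendar:

1. **Cleaning** — class-Z removal, duplicate-timestamp adjustment
   (`clean_track()`);
2. **Plausibility filtering** — a speed/distance/angle (SDA) filter with a
   5 m/s threshold (`sda_filter()`);
3. **State-space regularization** — a continuous-time random walk
   x(t+Δ) | x(t) ~ N(x(t), σ²Δ·I₂) observed with Argos-class-dependent
   error y_i ~ N(x(t_i), τ²_c·I₂), fitted by exact Kalman likelihood in a
   local planar frame and smoothed onto a regular 2-h grid
   (`fit_ssm()`, `predict_regular()`);
4. **Movement metrics** — speed, bearing, cumulative distance, the move
   persistence index γ_t ∈ (0,1) (a logit-random-walk state-space model of
   autocorrelation in speed and direction, `fit_move_persistence()`), and
   time-spent-in-area on a 50 × 50 km equal-area grid (`accumulate_tsa()`);
5. **Phenology detection** — migrant classification at the 1,000-km
   displacement threshold, the 100% minimum-convex-polygon foraging area
   of the non-migrants, and the four event dates per migrant: departure
   (last exit from the foraging polygon), arrival (first decelerating
   position south of 45°N, via a loess-smoothed speed curve, span 0.2),
   breeding departure (re-crossing the cohort mean arrival latitude) and
   return (re-entry into the foraging polygon) (`detect_phenology()`);
6. **Dive summaries** — Wildlife-Computers-style 6-h binned histograms and
   single random dives under both tag bin configurations, with phase
   assignment and per-phase statistics (`bin_dive()`, `assign_phase()`,
   `phase_dive_summary()`);
7. **Synthetic data** — a generator that emulates the multi-phase movement
   (foraging → southbound transit → breeding roaming → northbound return),
   Argos sampling error and transmission gaps, and binned diving, carrying
   ground truth for every stage (`simulate_cohort()`, `simulate_dives()`).

## Worked example

Simulate a tagged cohort and run the full pipeline (the `analysis/`
scripts run exactly this, at the study scale of 12 migrants and 14
residents):

```r
library(whalemigrate)

sim <- simulate_cohort(sim_config(seed = 7, n_migrants = 12,
                                  n_non_migrants = 14))
out <- run_pipeline(sim$tracks, "results/pipeline", loess_span = 0.2)
out$speed_summary
#> # A tibble: 5 × 4
#>   phase        n mean_kmh sd_kmh
#>   <chr>    <int>    <dbl>  <dbl>
#> 1 N-S       4353     4.80   1.08
#> 2 S-N       4807     4.50   1.07
#> 3 breeding 10170     3.49   1.14
#> 4 foraging 11335     1.37   1.03
#> 5 unknown   2760     3.02   1.73
```

The per-phase 2-h speeds recover the generator's movement regimes: fast
directed transit (≈4.8 km/h southbound), slower breeding-area roaming
(≈3.5 km/h), and slow area-restricted foraging. `out$phenology$records`
holds one row per migrant — the four event dates, whole-day leg durations
(N-S + breeding + S-N = whole cycle exactly), per-leg cumulative
distances and the maximum displacement from tagging. Comparing against
`sim$truth_table` (script `analysis/03_phenology.R`) shows departures and
arrivals dated within ±2 days of truth for every detectable animal in
this cohort; one simulated whale foraged outside the polygon delineated
by the residents and has no detectable departure, the same missing-event
pattern real deployments produce.

Move persistence separates the regimes on the behavioural axis
(`analysis/04_movement.R`):

```
phase        n mean_gamma sd_gamma
N-S       4349      0.921   0.0183
S-N       4805      0.918   0.0151
breeding 10163      0.881   0.0196
foraging 11314      0.576   0.0936
```

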