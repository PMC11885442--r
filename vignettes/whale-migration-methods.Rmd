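---
title: "Methods: from Argos fixes to migration phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Argos fixes to migration phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`whalemigrate` implements a complete analysis chain for Argos satellite
telemetry from deep-diving whales tagged at high latitudes: plausibility
filtering, state-space regularization, movement metrics, a
migration-phenology detector, and summaries of tag-transmitted binned dive
records, together with a synthetic-data generator that makes every stage
testable against known ground truth. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the validation on synthetic data does and does not demonstrate.

## The data and their pathologies

Doppler-derived Argos positions arrive irregularly (whales surface
briefly), with errors from a few hundred metres (class 3) to tens of
kilometres (classes A/B), occasional failed localizations (class Z),
duplicate timestamps, and multi-day transmission gaps. Every downstream
quantity — speed, residency, event dates — is distorted by these
pathologies unless they are modelled away, which is the purpose of the
first three stages.

**Cleaning** (`clean_track()`): class-Z fixes are removed first; any
timestamp not strictly later than its predecessor is then shifted forward
by one second, repeatedly, until timestamps strictly increase. Removing Z
before adjusting duplicates is a choice (the two operations commute in all
but contrived cases); doing it first avoids letting a failed localization
displace the timestamp of a valid fix.

**SDA filter** (`sda_filter()`): a speed/distance/angle plausibility
filter. An interior fix is implausible if the *smaller* of its implied
great-circle speeds to both retained neighbours exceeds `vmax` (default
5 m/s, roughly twice a sustained whale travel speed), or if it forms an
out-and-back spike: turning angle below 15°/25° with both legs longer
than 2,500/5,000 m. Using the minimum neighbour speed means a genuine
relocation (level shift) is kept while a spike is not. When several fixes
violate simultaneously we remove the single worst offender (highest
implied speed, ties broken by smallest angle) and re-evaluate — a
deterministic order that makes the filter a fixed point: re-filtering its
output removes nothing. Consecutive fixes separated by more than
`gap_exempt_h` (72 h) are exempt from the speed test; over such gaps the
straight-line speed no longer bounds plausibility.

## The state-space model

Filtered fixes are still irregular and noisy. We model the latent position
as a two-dimensional continuous-time random walk (Brownian motion) with
process SD $\sigma$ (km per $\sqrt{\text{hour}}$), observed with isotropic
Gaussian error whose SD depends on the location class:

$$x(t+\Delta) \mid x(t) \sim N\!\big(x(t),\ \sigma^2 \Delta I_2\big),
\qquad y_i \sim N\!\big(x(t_i),\ \tau^2_{c_i} I_2\big).$$

The model is fitted in a local azimuthal equidistant plane centred on the
track centroid: a random walk in raw longitude/latitude degrees is badly
distorted at 70–79°N, where a degree of longitude is a third of a degree
of latitude. The two planar coordinates are conditionally independent, so
filtering reduces to two scalar Kalman recursions over the irregular fix
times; $\sigma$ is estimated by maximizing the exact marginal likelihood
with a bounded univariate optimizer. A fixed Gaussian prior
(SD `p0_sd_km` = 100 km, centred on the first fix) initializes the state —
effectively diffuse, but proper, so the likelihood is well defined and the
smoother admits an exact dense-matrix oracle (the test suite checks
log-likelihood and smoothed states against a generalized-least-squares
solve to 1e-6).

Class error SDs default to literature-typical one-sigma values for
Kalman-processed Argos data (0.25, 0.5, 1.5, 5, 5, 10 km for classes
3, 2, 1, 0, A, B); they are configuration, not estimates, because a single
track rarely identifies per-class error scales.

**Prediction** (`predict_regular()`): a Rauch–Tung–Striebel smoother over
the fix times augmented with a regular 2-h grid, producing positions and
uncertainties on two datasets: *whole-track* (one grid spanning the full
deployment, predicting across gaps with correspondingly inflated
uncertainty — used for distances, displacement and event dating, so a gap
cannot hide an exit) and *segments-only* (grids laid only inside segments
— used for behavioural metrics, so inference never reaches into data
holes).

**Segmentation** (`segment_track()`): tracks split at gaps > 72 h; windows
must last ≥ 4 d and average ≥ 1 location per day spanned. We read the
daily-coverage rule as an average density rather than a strict
every-calendar-date requirement: under the strict reading, any sub-72-h
gap that straddles two empty calendar dates would discard an arbitrarily
long window, contradicting the 72-h split threshold that deliberately
tolerates such gaps. The strict variant remains available
(`segment_rules(per_date = TRUE)`).

## Movement metrics

Speeds are straight-line great-circle displacements between consecutive
2-h positions, computed only within segments; they are acknowledged
underestimates (whales neither travel in straight lines nor in two
dimensions). Cumulative distances accumulate over the whole track, with
straight-line bridging across segment joins. Bearings are initial
great-circle azimuths from the migration start. All spherical geometry
uses radius 6371 km.

**Move persistence** (`fit_move_persistence()`): a time-varying index
$\gamma_t \in (0,1)$ of autocorrelation in speed and direction. With
displacement vectors $d_t$ between consecutive 2-h positions,

$$d_t = \gamma_t\, d_{t-1} + e_t, \quad e_t \sim N(0, \sigma_p^2 I_2),
\qquad \operatorname{logit}(\gamma_t) \sim \text{RW}(\sigma_g).$$

$\gamma \approx 1$ is directed transit; $\gamma \approx 0$ is
area-restricted movement. Estimation is by Laplace-approximated marginal
likelihood over $(\sigma_p, \sigma_g)$ with a Newton inner solve for the
logit series (Gauss–Newton curvature; the penalized Hessian is
tridiagonal per segment chain, so each inner iteration is linear in the
series length). When several animals are supplied the variance pair is
pooled across them, making $\gamma$ comparable between individuals. On
synthetic tracks with AR(1) velocity correlation r ∈ {0, 0.5, 0.9} the
estimated mean $\gamma$ tracks r closely and monotonically. Logit values
are clamped to ±12; beyond that the likelihood is flat and a noiseless
track would otherwise push the optimizer to infinity.

**Time in area** (`accumulate_tsa()`): hours of track time on a 50 × 50 km
grid in a Lambert azimuthal equal-area plane (equal-area, so "50 km cell"
means the same thing at 75°N and 30°N; the projection origin defaults to
the data centroid). Each 2-h step is split among the cells it crosses in
proportion to sub-segment length — exact line clipping, chosen over
endpoint-cell assignment because it conserves time by construction
(per-segment cell-hours equal segment hours to floating-point accuracy)
and is robust at cell borders. Zero-length steps credit their containing
cell. Analyst exclusions (outlier animals) are an explicit configuration
list in `run_pipeline()`, never hard-coded.

## The phenology detector

The core analysis dates four events per animal.

1. **Migrant classification**: maximum great-circle displacement from the
   tagging location, threshold 1,000 km (the antimode of the strongly
   bimodal displacement distribution; the boundary value classifies as
   migrant).
2. **Foraging polygon**: the 100% minimum convex polygon over the
   non-migrants' fixes, subsampled to one location per two days to reduce
   serial autocorrelation. Convexity makes the closed-boundary
   point-in-polygon test trivial and exact (vertices and edges count as
   inside).
3. **Departure**: the first polygon exit not followed by a re-entry —
   unless the whale reached the breeding grounds (south of 45°N) in
   between, in which case the re-entry is the northbound return and the
   exit still counts. Detection runs on the whole-track dataset so
   transmission gaps cannot hide the exit.
4. **Arrival**: the first 2-h position south of 45°N (the classical
   delineation of North Atlantic breeding grounds) at which the whale is
   decelerating: negative first derivative of the loess-smoothed speed
   (span 0.2, degree 2, tricube weights; derivative by central differences
   on the fitted curve — simpler and easier to test than analytic
   derivatives of the local fits, and any difference is far below the
   day-scale resolution of the events). Speeds come from the
   segments-only dataset, so the criterion is never evaluated on
   interpolated gap traverses.
5. **Breeding departure**: the first post-arrival position north of the
   cohort mean arrival latitude. "Cohort mean" is the default reading (a
   per-individual variant is available); it judges leaving against the
   same latitude band the cohort entered through, and reduces to the
   whale's own arrival latitude for a single-animal cohort.
6. **Return**: the first re-entry into the foraging polygon afterwards.

Durations are whole-day calendar differences (GMT) of event dates, so the
four legs are exactly additive when all events are observed. Cohort
summaries report mean ± sample SD rounded to whole days; the span of
departure dates is a day-of-year range, since departures from different
years are compared within the annual cycle.

## The synthetic cohort: what it emulates, and what passing shows

The generator (`simulate_cohort()`) writes the statistical structure the
analysis assumes: Ornstein–Uhlenbeck home-range movement around foraging
centres on the shelf-edge tagging line (stationary SD 50 km, relaxation
tuned so foraging-phase 2-h speeds average ~2 km/h); a biased correlated
walk south-west at 4.7 km/h (the observed southbound transit speed) toward
a breeding destination at 26–38°N; slower correlated roaming (3.5 km/h)
south of 45°N for a residency drawn from the observed 51–102 d range; a
northbound return at 4.4 km/h; Argos sampling with a B-heavy class mix,
class-dependent noise, and Poisson/log-normal transmission gaps sized to
produce occasional >72-h holes; and per-phase dive records from truncated
normals with the observed phase means (expected sample means follow the
truncated-normal closed form, since depths must clear the tag's ignore
threshold).

Ground-truth events use the same geometric semantics the detector
measures: arrival is the true path's southbound 45°N crossing, breeding
departure its northbound re-crossing, return its approach within two
home-range SDs of the foraging centre. Truth departure is the behavioural
switch into transit; the detector's polygon exit necessarily lags it by
the boundary-crossing time (typically under a day at transit speed).

On seeded 20-migrant cohorts the pipeline classifies migrants perfectly
and dates departures and arrivals within ±2 d for ≥90% of animals, returns
within ±3 d, and reconstructs leg distances within 5% of the true path
length over the same interval. Two genuine failure modes survive — both
faithful to the method, not artefacts of it: a migrant whose foraging
positions happen to fall outside the polygon delineated by the residents
has no polygon exit to date, and a >72-h transmission gap spanning the
45°N crossing defers arrival detection to the next segment. Both occur at
a few percent per cohort and correspond to the missing-event rows real
deployments produce.

What passing does **not** show: the generator has no bathymetry, currents,
or behaviourally mechanistic diving; its Argos errors are Gaussian
(real class-B errors are heavy-tailed); its phase switches are sharp. The
validation therefore certifies the *pipeline logic* — filtering,
smoothing, geometry, event semantics, arithmetic — not the ecological
fidelity of any particular field dataset.

## Problem sizes and numerical choices

The bundled analyses and tests run cohorts of 12–30 animals with 2,000–
3,000 fixes per animal over 150–300-day deployments — comparable to a real
multi-year tagging programme — and complete in tens of seconds on a single
CPU, because every per-track operation is linear in track length (scalar
Kalman recursions, linked-list SDA filtering, tridiagonal Newton solves).
Likelihood optimization tolerances are 1e-9 (univariate $\sigma$) and
1e-7 relative (Nelder–Mead over the persistence variances); the inner
Newton solve stops at 1e-8 on the logit series. Degenerate inputs are
handled explicitly: an all-identical-fix track drives $\sigma$ to the
search boundary without crashing, collinear point sets raise a typed
degenerate-geometry error, empty phases yield empty summaries, and a
zero-day leg (identical event dates) is flagged as suspicious rather than
silently accepted.
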