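# marlintrack

Movement-ecology analysis of double-tagged pelagic fish — Argos
satellite-linked radio telemetry (SLRT) positions interleaved with pop-up
satellite archival tag (PSAT) light/SST geolocations. The two data streams
have radically different error structures: Argos classes span sub-km to
tens of km, while geolocation errors are heavy-tailed and strongly
anisotropic (latitude error ≫ longitude error, order 100 km). `marlintrack`
turns such irregular, error-prone location records into regular trajectories
and behavioural inferences:

1. **Regularization** — a continuous-time correlated random walk (CTCRW)
   state-space model with Ornstein–Uhlenbeck velocity,
   `dv = -β v dt + σ dW`, discretized exactly over irregular gaps, fitted by
   maximum likelihood (Kalman prediction-error decomposition) with
   class-specific measurement error, then smoothed onto a fixed 12-h grid.
2. **Behavioural classification** — each 12-h step's speed and turning angle
   feed a 4-component product mixture (gamma speeds × wrapped-Cauchy turns)
   fitted per animal by EM; steps are labelled slow/fast-transit or
   slow/fast-ARB (area-restricted behaviour) by maximum component
   likelihood, with run-length smoothing and bout statistics.
3. **Capture effects** — Kaplan–Meier time to first ARB (Greenwood variance,
   log–log CI) with its 50:50 crossing day; early-vs-late rank-sum speed and
   heading contrasts (Hodges–Lehmann shifts); seasonal return-to-capture
   classification.
4. **Depth** — day/night aggregation of 12-bin PSAT time-at-depth summaries
   onto common bins, local-linear gap filling on the simplex, and a
   rank-sum contrast of period maximum depths between transit and ARB.
5. **Synthetic data** — a mode-switching movement and depth generator with
   Argos-class and heavy-tailed geolocation errors, observation gaps and
   binned depth summaries, so the whole chain is testable against known
   truth without access to tag data.

A verbatim transcription of the study's 25-deployment summary table ships as
a package fixture (`read_table1_fixture()`).

## Worked example

```r
library(marlintrack)

d <- tempfile()
rep <- run_pipeline(list(seed = 42, out_dir = d, n_animals = 2, restarts = 5,
                         sim = list(duration_days = 40, obs_rate_per_day = 4)))
writeLines(make_report(d)$markdown)
```

```
# Pipeline run report

- Mean ARB bout duration: 3.64 days
- Modes per individual: 4, 4
- KM 50:50 crossing: day 1.0
- Surface time day/night: 0.512 / 0.647

## Deployment table
- 25 animals, mean weight 79.8 kg
- Totals: 1431 days at liberty, 799 SLRT days, 973 PSAT days
```

Reading the output: two 40-day synthetic animals were simulated, smoothed
onto 12-h steps, and classified; ARB bouts averaged 3.6 days and both
animals expressed all four modes. The Kaplan–Meier curve over the two
animals crosses 50% on day 1 (with ARB allowed from release and only two
subjects, onset is immediate — the capture-effect analyses are meant for
cohorts of ~25 animals, as in the acceptance script). Simulated surface time
is lower by day (51.2%) than by night (64.7%), matching the generator's
configured day/night structure. The deployment-table section summarizes the
packaged 25-row fixture: mean fish weight 79.8 kg and 1431 total days at
liberty.

Individual stages are plain functions: `read_locations()`, `fit_ctcrw()`,
`smooth_predict()`, `step_metrics()`, `fit_movement_mixture()`,
`classify_steps()`, `km_estimator()`, `aggregate_tad()`, … — see the
methods vignette (`vignettes/marlintrack-methods.Rmd`) for the models,
parameter defaults and design rationale. A thin CLI wrapper lives at
`inst/scripts/mtrack.R`.

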