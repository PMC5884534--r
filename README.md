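# dynocc

Dynamic occupancy and diel activity analysis for camera-trap surveys.

`dynocc` is for ecologists analysing repeat-survey camera-trap data of a
species that is detected imperfectly — the motivating case is an invasive
American mink population on a remote island, surveyed at ~93 fixed stations
over several seasons. The package answers two linked questions: **where**
the species is (how site occupancy changes across seasons and habitat
covariates, correcting for imperfect detection) and **when** it is active
(how detections distribute over the 24-h day relative to the time
available).

## The models

**Occupancy.** Each site `i` has a latent occupancy state per season,
`z(i,t) ∈ {0,1}`, following a two-state Markov chain

    z(i,1) ~ Bern(ψ₁(i))
    z(i,t) | z(i,t−1) ~ Bern( z(i,t−1)·(1−ε(i,t)) + (1−z(i,t−1))·γ(i,t) )

with detection `y(i,t,k) ~ Bern(z(i,t)·p(i))` over `K` secondary periods
(default four 5-day periods per season). ψ₁ (initial occupancy),
γ (colonization), ε (extinction) and p (detection) all take covariates on
the logit scale. Dynamics may additionally depend on the neighbourhood
auto-covariate `D(i,t) = mean of z(j,t) over neighbours j`, computed from
the previous season's states. Models without the auto-covariate are fitted
by adaptive Metropolis on the *exact marginalized likelihood* (latent
states recovered by forward-filter backward-sampling); auto-covariate
models use a latent-state Gibbs + Metropolis sampler. Model structure is
chosen by staged forward selection on DIC (detection → initial occupancy →
colonization → extinction), with a collinearity screen (|Spearman ρ| ≥ 0.7)
refusing redundant covariate pairs.

**Activity.** Independent detections (>60 min apart per station) give clock
times on the 24-h circle. A von Mises kernel density estimates the activity
pattern; the day is partitioned into dawn/day/dusk/night from seasonal mean
sun times (dawn and dusk are sunrise/sunset ± 2 h); and design-I selection
ratios `w = use/availability` with Bonferroni simultaneous intervals
classify each period as selected (`lower > 1`), avoided (`upper < 1`) or
used as expected.

Because the motivating survey deposits no raw data, the package ships a
synthetic-study generator (`simulate_study()`, `synthetic_truth()`) that
emulates the design — 93 stations in three habitats, 4 seasons with only 47
stations operative in winter, covariate-driven dynamics, night-concentrated
winter activity — with the generating values retained for recovery tests.

## Worked example

```r
library(dynocc)

stations <- simulate_landscape(n_stations = 93, seed = 11)
design   <- default_design(stations$id, seed = 11)
truth    <- synthetic_truth(seed = 11)
sim      <- simulate_dynamics(truth, stations, design, seed = 11)

events  <- filter_independent(sim$events, min_gap_minutes = 60)
history <- build_history(events, design, stations)
print(history)
#> Detection history: 93 sites x 4 seasons x 4 secondary periods
#>   277 site-period detections; 46 site-seasons missing; 6520 total trap nights

collinearity_screen(stations,
  c("elevation", "slope", "dist_coast", "dist_any_water", "ground_cover"))
#>        cov1       cov2       rho
#> 1 elevation dist_coast 0.8750053

dyn <- subset_history(history,
                      seasons = c("summer2014", "spring2014", "summer2015"))
fit <- fit_dynamic(occu_spec(psi1 = ~elevation, p = ~ground_cover),
                   dyn, stations,
                   control = mcmc_control(n_chains = 2, n_iter = 1500,
                                          n_burn = 500, seed = 11))
summary(fit)
#> Posterior summary (logit-scale coefficients):
#>                       mean    sd  lower median  upper  rhat
#> psi1.(Intercept)     0.387 0.330 -0.220  0.374  1.076 1.064
#> psi1.elevation      -1.362 0.352 -2.056 -1.379 -0.668 1.020
#> gamma.(Intercept)   -1.191 0.279 -1.746 -1.168 -0.674 1.051
#> epsilon.(Intercept) -0.486 0.239 -1.001 -0.487 -0.032 1.002
#> p.(Intercept)       -0.202 0.110 -0.404 -0.209  0.024 1.008
#> p.ground_cover       0.406 0.118  0.177  0.412  0.633 1.021
#>
#> DIC 980.7 (pD 5.9, mean deviance 974.8; marginal scale)
#>
#> Proportion of sites occupied (posterior mean [95% CrI]):
#>   summer2014   0.579 [0.527, 0.645]
#>   spring2014   0.458 [0.419, 0.505]
#>   summer2015   0.408 [0.376, 0.462]
```

The elevation coefficient on initial occupancy is negative (−1.36, CrI
excluding 0): occupancy is highest near sea level, as simulated. The ground
cover coefficient on detection is positive (0.41). The PAO lines are the
finite-sample proportion of the 93 sites occupied per season, computed from
the posterior latent-state draws, with detection failure corrected for —
they track the realized simulation truth, not the raw detection frequency.

Winter diel activity, from the same generator:

```r
sun <- simulate_sun_times(design$seasons$start[2] + 0:19)
hrs <- simulate_activity_times(120, truth$diel$winter2014, seed = 12)
activity_analysis(hrs, sun, kappa = 30)$ratios
#>   period        use availability          w         se    lower     upper classification
#> 1   dawn 0.03693643    0.1666667 0.22161859 0.10330363 0.000000 0.4796406        avoided
#> 2    day 0.01033134    0.1247916 0.08278873 0.07396857 0.000000 0.2675404        avoided
#> 3   dusk 0.03321609    0.1666667 0.19929652 0.09815209 0.000000 0.4444515        avoided
#> 4  night 0.91951615    0.5418751 1.69691538 0.04582941 1.582447 1.8113837       selected
```

Night holds 92% of the activity mass against 54% availability
(w = 1.70, simultaneous CI excluding 1): night is *selected* and daytime
*avoided* — the winter-like pattern the generator encodes.

The whole analysis is also available as a config-driven pipeline
(`run_simulate()`, `run_fit()`, `run_report()`; thin CLI in
`inst/scripts/dynocc`): one YAML file governs inputs, MCMC sizes, stage
candidates and seeds, and every output file carries the config hash and
seed in its header.

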