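---
title: "Methods: dynamic occupancy and diel activity from camera traps"
author: "dynocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic occupancy and diel activity from camera traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynocc)
```

`dynocc` analyses repeat-survey camera-trap data for a species that is
detected imperfectly — here motivated by surveys of an invasive semi-aquatic
mustelid on a sub-Antarctic island, but applicable to any design with fixed
stations revisited over seasons. This vignette describes the models, the
estimation machinery, the synthetic-data generator used for validation, and
the numerical and design choices that a user or maintainer should know
about.

## The state-space occupancy model

Each site $i$ carries a latent occupancy indicator per season $t$,
$z(i,t) \in \{0,1\}$. The ecological process is a two-state Markov chain:

$$z(i,1) \sim \mathrm{Bern}(\psi_1(i)), \qquad
  z(i,t) \mid z(i,t-1) \sim \mathrm{Bern}\!\big(z(i,t-1)(1-\epsilon(i,t)) +
  (1-z(i,t-1))\,\gamma(i,t)\big),$$

with $\psi_1$ the initial occupancy probability, $\gamma$ the colonization
probability of an empty site, and $\epsilon$ the extinction probability of
an occupied one. The observation layer is the usual imperfect-detection
Bernoulli: within season $t$ the camera record is collapsed into $K$
secondary periods (by default four 5-day periods, so 20 trap nights per
operative station per season) and
$y(i,t,k) \sim \mathrm{Bern}(z(i,t)\,p(i))$. Missing observations (stations
not operative in a season) contribute likelihood 1 — the standard
missing-at-random treatment; they are never imputed. All four probability
parameters take covariates through a logit link; quadratic terms are written
`I(x^2)` on the standardized scale.

The closure assumption (no change of state within a season) and
independence between stations' observation errors are inherited from the
survey design, not checked by the package.

### The spatiotemporal auto-covariate

Dynamics may depend on the neighbourhood: with $N_i$ the set of neighbours
of site $i$ and $n_i$ its size, $D_{i,t} = n_i^{-1}\sum_{j \in N_i} z_{j,t}$
is the fraction of occupied neighbours. When requested, $D$ computed from
the *previous* season's states enters the linear predictors of $\gamma$
and/or $\epsilon$ for the transition into the current season — the
transition out of state $t-1$ conditions on the field at $t-1$, which is
also exactly how the synthetic generator simulates it. Neighbourhoods are
all stations within a planar Euclidean radius; the default 1,500 m sits
between the typical inland (~810 m) and coastal (~2,000 m) station spacings
and is an analysis choice to be varied, not an estimated quantity. Isolated
sites get $D = 0$ with a warning.

## Estimation

Priors are independent Normal(0, sd 31.6) on every logit-scale coefficient,
the diffuse precision-0.001 convention of standard Bayesian occupancy
workflows; the sd is a `mcmc_control()` argument.

Two engines are used, chosen automatically:

* **Marginalized likelihood** (no auto-covariate). Sites are conditionally
  independent, so the likelihood marginalizes the latent chain exactly by a
  per-site forward recursion over the two states, with per-season
  renormalization for numerical stability. Sampling is adaptive random-walk
  Metropolis (joint proposals; covariance adapted from the burn-in history,
  frozen afterwards). Latent-state draws for derived quantities are
  recovered afterwards by forward-filter backward-sampling at a thinned
  subset of the posterior draws. The same marginal likelihood powers a
  maximum-likelihood cross-check (`fit_occu_ml()`), and the test suite
  verifies the recursion against brute-force enumeration over all latent
  configurations on small problems (tolerance 1e-10) and against an
  independent JAGS fit.

* **Latent-state sampler** (auto-covariate present). $D$ couples sites
  through their neighbours' latent states, breaking the factorization, so
  the sampler alternates exact single-site Gibbs updates of $z(i,t)$ —
  whose full conditionals include the terms through which $z(i,t)$ enters
  each neighbour's next transition — with Metropolis updates of the
  coefficients given $z$.

Convergence is assessed with split Gelman–Rubin $\hat R$ per coefficient
(each chain halved, so within-chain drift inflates the statistic); a fit
with any $\hat R$ above 1.1 is flagged, not rejected. Defaults are
test-scale (3 chains, 2,000 kept after 500 burn-in);
`mcmc_control(paper_scale = TRUE)` reproduces the survey-scale convention
of 100,000 kept draws after a 20,000 burn-in.

Derived quantities are finite-sample functionals of the latent draws:
`pao()` is the per-draw fraction of occupied sites (overall or restricted
to, say, coastal vs inland stations) with 95% quantile intervals, and
`response_curve()` back-transforms a coefficient's linear predictor over a
raw covariate grid through the stored standardization, holding other
covariates at their mean.

## Model selection

`dic()` uses the Spiegelhalter plug-in definition — $p_D = \bar D - D(\bar\theta)$,
$\mathrm{DIC} = \bar D + p_D$ — matching the JAGS convention. For
marginalizable fits the deviance is the exact marginal deviance; for
auto-covariate fits it is conditional on the latent states, and the two
scales are *not* comparable (the selection table flags conditional-scale
rows).

`forward_select()` implements a staged forward procedure: detection first,
then initial occupancy, then colonization and extinction, each stage
freezing the previous winners. Within a stage every single term-unit
candidate is fitted; a candidate is informative iff its DIC is below the
stage null's, the best informative unit is added, and the procedure
continues while DIC decreases. Ties break toward the simpler model;
candidates that combine a collinearity-flagged covariate pair (default
screen: |Spearman rho| ≥ 0.7) are skipped; candidates whose fit fails the
$\hat R$ threshold are excluded with a note. The audit table of every fitted
model is the primary product — DIC differences in hierarchical models are
suggestive rather than definitive, and a final override is left to the
analyst.

A property worth knowing: selecting by raw DIC admits a spurious covariate
in roughly 16% of cases asymptotically ($P(\chi^2_1 > 2)$), and more when
Monte Carlo noise in the deviance is non-negligible — in our simulations at
93 stations with short test-scale chains the false-admission rate is around
0.3 per candidate, dropping toward the asymptotic rate with longer chains.
Null-model retention across a multi-candidate, multi-stage menu therefore
decays geometrically; the package's validation checks null retention on the
minimal single-candidate detection stage with 3×2,000 chains, and treats
the stage table, not the winner alone, as the deliverable.

## Diel activity

Detections thinned to independence (strictly more than 60 min between kept
events per station, greedy forward pass) yield clock times on the 24-h
circle. The day is partitioned by the season's mean sun times (circular
means over the operative days): dawn = sunrise ± 2 h, dusk = sunset ± 2 h,
day between dawn and dusk, night the remainder. The four half-open
intervals tile the circle; dawn and dusk are exactly 4 h; availabilities
are interval lengths over 24.

`circular_kde()` is a von Mises kernel density on clock time (not solar
time — camera timestamps are clock time; sun times enter only through the
partition), evaluated on a 512-point grid, trapezoid-normalized to
integrate to 1. The concentration $\kappa$ defaults to maximizing the
leave-one-out cross-validated log-likelihood over a log-spaced grid
(multiplied by `adjust`, default 1), and is fixed numerically in tests for
reproducibility.

`selection_ratios()` implements population-level (design-I) selection:
$w_i = o_i / \pi_i$ compares use against availability,
$SE(w_i) = \sqrt{o_i(1-o_i)/(n\pi_i^2)}$, and simultaneous confidence
intervals use the Bonferroni quantile $z_{1-\alpha/(2I)}$ over the $I = 4$
periods, with lower bounds truncated at zero. A period is *selected* when
the lower bound exceeds 1 and *avoided* when the upper bound is below 1.
"Use" defaults to the KDE per-period mass (with $n$ = number of independent
detections supplying the SE); a raw-count mode is provided because either
reading is defensible, and the two agree as smoothing decreases. Repeat
detections of unidentifiable individuals are potential pseudoreplication;
no correction is applied.

The Wald-type SE makes the simultaneous intervals slightly anticonservative
at small samples (simulated joint coverage ≈ 0.94 around n = 150–400 under
no selection) and conservative in the large-n regime; the package's
coverage validation is run at n = 2,000 detections per replicate for that
reason, and small-sample interval behaviour is asserted separately at its
observed level.

## The synthetic-study generator

Because the motivating survey deposits no raw data, validation runs on
synthetic studies with retained ground truth (`synthetic_truth()`,
`simulate_study()`). The generator emulates the design's statistical
structure:

* **Landscape** — 93 stations by default, split roughly 20/38/35 between
  coastal shrubland, forest and meadow; coastal stations strung along a
  coastline at 1,363–2,782 m spacings, inland stations on a five-row
  jittered grid at ~810 m spacing so the distance-to-coast range does not
  grow with n. Elevation increases with distance to coast with noise
  calibrated once so the two are rank-correlated at rho ≈ 0.87 — strong
  enough that the default collinearity screen must flag the pair, as the
  analysis workflow expects.
* **Seasons** — two summers, one winter, one spring; four 5-day secondary
  periods each; only about half the stations (47 of 93) operative in
  winter, entering the models through the effort mask.
* **Dynamics and detection** — logit-scale coefficients chosen inside
  plausible ranges for the system: initial occupancy around 0.55–0.6
  declining with elevation, detection ~0.4 at the mean raised by ground
  cover and depressed by distance to water, colonization ~0.2 and
  extinction ~0.3 driven by distance to water, auto-covariate off by
  default (configurable).
* **Events** — each detected secondary period yields a zero-truncated
  geometric number of timestamped events (p = 0.5), uniform over the
  period's days, with clock times from the season's diel mixture: uniform
  in summers; a von Mises (mean 01:30, kappa 2–2.5) mixed with a uniform at
  weight 0.8–0.85 in winter/spring, which concentrates roughly 80% of
  events in the night period. No within-period event model is implied by
  the motivating design; this one is the simplest that exercises the
  independence filter and the activity pipeline.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about field data: spatial autocorrelation in covariates
beyond the elevation–coast pair, individual movement or home ranges (events
are conditionally independent given z), weather-driven detectability
drift within seasons, camera failures mid-season, or misidentification.

## Numerical choices and degenerate inputs

* Standardization uses the sample (n−1) standard deviation; the scaling is
  stored in the fit for back-transformation, and constant columns are an
  error.
* The independence filter is a greedy forward pass anchored on kept events;
  an event exactly at the 60-min gap is discarded (strict inequality). The
  rule is applied per station; the gap is configurable.
* Secondary periods and distance bins are half-open, left-closed;
  `[50, 100)` receives a station at exactly 50 m. Zero-effort distance bins
  report an undefined (NA) rate, never 0.
* Secondary periods align to each station's deployment start (season start
  plus optional per-station offset), accommodating surveys run in
  sequential station groups.
* The forward recursion renormalizes per season, so likelihoods of long
  series cannot underflow; non-finite parameters are an error.
* The latent sampler pins $z = 1$ wherever a detection was observed (its
  full conditional is degenerate there).
* Timestamp parsing is strict ISO 8601 with a round-trip check, so
  impossible dates (month 13) are an error naming the row rather than a
  silent roll-over.
* Seeds: every simulator and sampler takes an explicit integer seed;
  stream-specific seeds are derived with 31-bit modular arithmetic so all
  derived seeds remain valid R integers.

## Problem sizes used in validation

The shipped test-suite and acceptance script exercise: brute-force
likelihood enumeration at ≤4 sites × ≤3 seasons (100 random instances);
parameter recovery at 300 sites × 3 seasons × 4 surveys (10 replicates,
intercept-only, posterior means within 0.07 of truth); single-season
covariate recovery at 300 sites; selection consistency at 93 stations × 3
seasons (20 replicates); Bonferroni coverage over 2,000 multinomial
replicates; and a full pipeline run at the 93-station study scale. These
sizes were chosen to give the properties enough statistical resolution
while keeping a full validation run in minutes on a single core.

## Known limitations

* Covariates are site-level only: season-varying covariates (and hence
  season-specific coefficients for $\gamma$/$\epsilon$ beyond the
  auto-covariate's time variation) are not supported.
* DIC for auto-covariate models is on the conditional scale and cannot be
  compared with marginal-scale DICs; the selection table flags this rather
  than resolving it.
* The latent-state sampler updates sites one at a time and is the slow
  path; it is intended for the ~100-station scale of the motivating
  design.
* No overlap coefficient between two activity distributions is computed;
  the activity module addresses single-sample seasonal patterns only.
* The sun-time generator is an astronomical approximation adequate for
  4-h-resolution period definitions, not an ephemeris.
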