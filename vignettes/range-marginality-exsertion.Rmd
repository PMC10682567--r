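---
title: "Range marginality and stylar exsertion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range marginality and stylar exsertion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lobexsert)
```

## The scientific problem

In *Lobelia*, the style must elongate out of the fused anther tube before the
stigma can receive outcross pollen, so the presence of an exserted style in a
photograph is a direct proxy for outcrossing capability. Community-science
platforms supply thousands of georeferenced photographs per species, and the
hypothesis under test — selection for reproductive assurance under mate
limitation — predicts that stylar exsertion should become rarer at high
latitudes and near a species' range margin. `lobexsert` implements the full
analysis pipeline for photo-scored occurrence records: validation and
filtering, a geodesic range-marginality index, covariate standardization,
binomial and Poisson regression with prediction surfaces and multiplicity-
adjusted species contrasts, and a synthetic generator with known truths so
that every stage can be verified by parameter recovery.

## The record model and filter cascade

A record is one scored plant: species code, WGS84 coordinates, observation
date, an exsertion score in `present` / `possible` / `absent` / `unscorable`,
counts of clearly visible and style-exserted flowers, fruit presence
(`yes` / `no` / `unscorable`), sex, and optional GPS accuracy and elevation.
Parsing enforces the invariants (coordinates in range, exserted ≤ visible,
`present` ⟺ at least one exserted flower when both are recorded,
`unscorable` ⟹ zero visible flowers) and reports a named diagnostic for every
rejected row; nothing is dropped silently. Species codes are a closed
enumeration so typos surface as diagnostics instead of phantom species.

The inclusion cascade runs in a fixed order — missing coordinates, then
non-hermaphrodite plants of the two gynodioecious species (females are
expected a priori to exsert, so they would bias the comparison), then
`possible` and `unscorable` scores, unscorable fruit, records without
clearly visible flowers, and finally (for the geographic models, where
elevation is a covariate) records lacking elevation. Each removed record is
charged to the *first* rule it fails, which makes the audit report
deterministic and its arithmetic close exactly. The count-model dataset
additionally keeps only `present` records with a recorded exserted-flower
count; a `present` record whose count was not recorded stays in the binary
dataset (it is informative for presence) but cannot enter the count model.
The cascade is idempotent, which the tests assert directly.

## The range-marginality index

For a species with occurrence coordinates \(\{(x_i, y_i)\}\), the range
center is the arithmetic mean of the longitudes and of the latitudes, and the
range boundary is the convex hull of all coordinate pairs. For a datapoint
\(p\),

\[ r(p) \;=\; \frac{d_{\mathrm{center}}(p)}{d_{\mathrm{center}}(p) + d_{\mathrm{margin}}(p)} \in [0, 1], \]

where \(d_{\mathrm{center}}\) is the great-circle distance to the center and
\(d_{\mathrm{margin}}\) the minimum great-circle distance to the hull
boundary. \(r = 0\) at the range center and \(r = 1\) on the range margin.

Numerical choices, all configurable or tested:

* Distances use the haversine formula on a sphere of radius 6 378 137 m (the
  default of the common geodesic toolchain for occurrence data); the radius
  is an argument everywhere.
* The hull is computed *planar* on raw longitude/latitude (the standard
  `chull` routine, reordered counter-clockwise, collinear vertices dropped),
  while distances to its edges are *geodesic* — a deliberate hybrid that
  replicates the established toolchain for this analysis rather than a fully
  spherical hull. Distance to an edge uses the cross-track distance when the
  spherical foot of the perpendicular lies within the arc and the nearer
  endpoint otherwise, via 3-D unit-vector projection.
* Interior and exterior points both use the unsigned boundary distance.
* A point exactly at the center returns exactly 0 and a point exactly on a
  vertex exactly 1: both component distances short-circuit on exact
  coordinate equality, so the endpoint identities hold to the last bit
  rather than to rounding error.
* Ranges spanning more than 180° of longitude (antimeridian wrap) are
  rejected; the five North American species do not wrap.
* The range model is always built from **all** coordinate-bearing records of
  the species, *before* trait filtering, since the range is inferred from
  the full spread of observations.

The boundary-distance kernel is verified in the tests against dense sampling
along each hull edge (10 000 points per edge by spherical interpolation) and
against an independent geodesic distance-to-polyline routine; hulls are
verified against a brute-force extremality oracle.

## Covariates and standardization

Day of year is the 1-based ordinal day (366 permitted in leap years — the
calendar routine's behavior, retained deliberately). All numeric predictors
are z-scored with the sample standard deviation so effect sizes are
comparable; day of year is additionally *group-centered* (z-scored within
species) in the among-species models to absorb differences in growing-season
timing. The fruiting flag stays 0/1: it is an indicator, not a measurement,
and the reported effect is per unit change of the flag. Standardization
parameters are estimated on each model's own fitting subset (binary and
count subsets separately, since they are separate models) and travel with
the fit; they serialize to JSON at 17 significant digits, which round-trips
IEEE doubles bit-identically, so prediction grids reuse fitting-time scales
exactly.

The geographic design is `z_latitude`, `z_marginality`, `z_longitude`,
`z_elevation`, `z_day_of_year`, `fruit_indicator` (plus
`z_total_visible_flowers` in the count model, since more visible flowers
mechanically allow more exserted ones). The species design uses indicator
coding with *inflata* as the reference level — the contrasts then read
directly against the focal species; marginal means are invariant to this
choice.

## Inference

Both families are fit by iteratively reweighted least squares with canonical
links. Convergence is declared when the maximum absolute coefficient change
falls below 1e-8 or the deviance change below 1e-10, with a 50-iteration
cap. Quasi-separation is an error, detected as any |linear predictor| above
30 or binomial fitted probabilities within 1e-10 of 0 or 1 — the latter
matters because under complete separation the IRLS steps stall before the
linear predictor reaches 30 while the deviance criterion declares
convergence. The covariance is the inverse Fisher information; inference is
Wald (z = β/SE, two-sided normal p), matching standard GLM summaries.
Dispersion is fixed at 1 for both families; a Pearson χ²/df diagnostic is
reported but never modeled. The count model is an ordinary Poisson fit on
the present-only subset (responses ≥ 1) rather than a truncated likelihood —
a faithful-replication choice that mirrors the original analysis; the
synthetic generator lets you measure the resulting attenuation rather than
assume it away. All intervals are 95%.

Prediction surfaces hold non-focal numeric predictors at their fitting-time
means (z = 0) and the fruiting flag at the fitting-subset mean proportion;
bounds are η ± 1.96·SE(η) inverse-linked, hence asymmetric on the response
scale, and grid values outside the observed predictor range are allowed but
flagged. Estimated marginal means evaluate each species at group-centered
day of year 0 and the *pooled* mean fruiting proportion (the pooled value is
what the among-species comparison holds constant; species-specific fruiting
rates are part of what the species effect absorbs).

Pairwise species contrasts are single-step adjusted against the
equicoordinate multivariate-normal reference of the contrast statistics —
the GLM analogue of the Tukey test. The adjusted p of contrast *i* is
P(max_j |Z_j| ≥ |z_i|) with the contrasts' correlation structure, estimated
by seeded Monte Carlo with 100 000 draws (default seed 20231127; the RNG
state of the session is saved and restored, so the adjustment never
perturbs user-level reproducibility). Because the C(k,2) pairwise contrasts
have rank k − 1, the reference vector is sampled through the full-rank
coefficient covariance and mapped through the contrast matrix rather than
factorizing the singular contrast covariance. At 100 000 draws the
Monte-Carlo standard error of an adjusted p is below 0.002. A deterministic
Bonferroni fallback is available, and the tests pin the estimate between
the raw p and the Bonferroni bound and against an independent single-step
implementation.

## The synthetic generator

The generator emulates the statistical structure the models assume, with
every truth recorded: locations uniform within a per-species range polygon
(rejection sampling; degenerate polygons are detected), dates uniform in a
per-species season window, elevation linear in latitude with Gaussian noise,
visible flowers 1 + Poisson(λ_V), fruiting Bernoulli on a logistic
day-of-year trend, presence Bernoulli on the logistic model in the z-scored
covariates, and — conditional on presence — a zero-truncated Poisson count
capped at the visible-flower count (the cap preserves the record invariant;
its attenuation of the count slope is measured by the recovery experiment,
not assumed absent). Contamination is overlaid last: records become
`possible` (counts hidden) or `unscorable` (all flowers obstructed, zero
visible) with configured probabilities, and plants of the gynodioecious
species are female with configured probability and forced to `present`.
Marginality enters the generative linear predictor exactly as the pipeline
computes it, on the realized point cloud.

Defaults are fixed once as the study conditions: presence coefficients
(−1.448, −0.644, −0.222, 0.286, 0.010, −0.168, 0.256) and count slope 0.326
on the z-scored scale; per-species sample sizes equal to the published
hermaphrodite datapoint totals; `p_possible = 0.08` (the focal species'
observed share of `possible` scores), `p_unscorable = 0.15` (between the
published per-species extremes of 13% and 35.7%); fruiting intercept
0.8 = logit(0.69), the published pooled fruiting probability; count
intercept 0 (zero-truncated mean ≈ 1.6 flowers at the average display,
within the published per-species range of 1.4–4.6); λ_V = 2.0;
`female_prob = 0.15`. The range polygons are five overlapping rectangles
spanning roughly 30–50° N — qualitative placeholders for continental
eastern North America, not estimated ranges.

What the generator does **not** emulate: spatial clustering of observers and
records, detection bias beyond the two contamination rates, spatial
autocorrelation of the residuals, species' true range shapes, or
measurement error in coordinates. Passing recovery tests therefore
demonstrate that the pipeline estimates what it claims under the stated
generative model — not that community-science data satisfy that model.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed: generation uses per-species
substreams derived from the base seed by fixed offsets, the Tukey
adjustment uses its own recorded seed, and the subcommand layer writes a
manifest (config echo, seed, input checksums, package version) next to
every output, so identical configurations reproduce byte-identical files.

The shipped tests run the recovery experiment at n = 2000 records and 200
replicates for both the published-coefficient configuration and an
all-zero-slope null — sizes chosen so the Monte-Carlo standard error of a
coverage estimate is about 1.5 percentage points while the whole experiment
stays under a minute; geometry oracles use 100 random point/hull pairs with
10 000 boundary samples per edge. Note one statistical caveat read directly
off the binomial distribution: at 200 replicates the standard error of a
rejection-rate estimate at the 5% level is ~1.5 points, so a perfectly
calibrated test still lands outside a ±2-point band around 5% roughly one
time in five per coefficient.

## Limitations

* The marginality index inherits the convex hull's behavior: concave range
  boundaries and disjunct populations inflate the apparent range, so `r`
  understates marginality for records near a concavity.
* The planar hull / geodesic distance hybrid is faithful to the established
  toolchain but is not a fully spherical computation; at continental scale
  the discrepancy is far below the index's ecological resolution.
* The count model ignores zero truncation, as in the original analysis;
  its intercept is therefore biased upward for small means, which the
  recovery experiment quantifies.
* No spatial random effects, interactions, or overdispersion modeling; the
  Pearson diagnostic tells you when that assumption is strained.

## Running the pieces

```{r example}
cfg <- synthetic_config(species = "inflata", n = c(inflata = 2000))
sim <- generate_records(cfg, seed = 42)
res <- run_geo_pipeline(sim$records, which_model = "binary")
wald_table(res$fit)
predict_surface(res$fit, "z_marginality", c(0, 1))

rec <- recovery_experiment(cfg, n_replicates = 200, seed = 1)
rec$summary
```
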