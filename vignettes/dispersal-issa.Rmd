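---
title: "Methods: dispersal-state segmentation and integrated step selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal-state segmentation and integrated step selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dispssa)
```

This vignette is the package's account of its science: the models, the
operational choices behind each stage, why the defaults are what they are,
and what the validation experiments do and do not establish.

## The problem

GPS collars on dispersing juveniles produce a fix every few hours over
months. Three questions structure the analysis: *when* is the animal in each
dispersal mode (residency, exploration, departure, transient home range);
*what* habitat does it select within each mode; and *do two populations
differ* in that selection. The package answers them with, respectively,
net-squared-displacement (NSD) segmentation, integrated step-selection
analysis (iSSA), and inverse-variance pooling with a two-site comparison.

## Track preprocessing

**Resampling.** Collars differ in duty cycle, so fixes are regularized to a
target interval (default 240 min) with a ±10-min acceptance window. The
matching rule is a greedy forward pass: from the current anchor, the
earliest fix whose gap falls inside the window is accepted and becomes the
new anchor; too-early fixes are skipped; an overrun closes the burst. Greedy
forward matching is deterministic and order-independent, and resampling an
already-regular series is the identity. Bursts need at least 3 fixes — the
minimum that yields one step with a defined turning angle.

**Kill-site clusters.** Stationary behavior (feeding at a carcass) violates
the movement model, so clusters are detected with three parameters: a
minimum of 4 member fixes, a 150 m spatial buffer, and a 24 h temporal
buffer. Membership is tested against the *running centroid* (recomputed as
members join), the linkage used by common kill-site cluster tools; the
temporal buffer is interpreted as the maximum gap between consecutive
members, not the total span, so multi-day kill sites persist; fixes that
wander off mid-cluster are skipped without closing the candidate (the
animal may leave and revisit within a day). Removal keeps the cluster's
first fix as the end of the incoming step and its last fix as the start of
the departing step; everything between is dropped, so no step ever spans a
stationary interval.

**Transition trimming.** The first 3 days of every classified state are
removed and the remainder re-bursted, so steps near a behavioral switch do
not contaminate state-specific fits. Time intervals are half-open
`[start, start + trim)`; all timestamps are UTC.

## NSD segmentation

Daily NSD uses one fix per calendar day — the fix nearest local noon — and
is the squared Euclidean distance (km²) from the natal-range origin. Days
without fixes stay absent; nothing is interpolated.

**Natal range.** The origin is the centroid of the first 30 days of daily
fixes (residency "longer than a month"), extended while the animal keeps
returning, and the radius is the 0.95 quantile of daily distances from the
origin. Residency itself is tested by drift: if the net shift between the
mean of the first five and last five daily positions of the window exceeds
1.5× the radius, the track is a monotone drift rather than home-ranging and
the animal is flagged and excluded — the same fate as field animals that
never displayed home-ranging around the capture site. The 1.5 margin
absorbs the sampling noise of five-day positional means, which for a range
of radius *R* is of order *R*/√5 per coordinate.

**Classification.** With threshold `return_threshold × radius²` (default
multiplier 1.0, with a 50 m floor on the radius so point-like ranges still
classify):

* days at or below threshold are **natal**;
* an excursion of at least `away_min_days` (default 7) that later re-enters
  is **exploratory**, labeled from its first day beyond threshold through
  the day before re-entry; shorter sallies remain natal noise;
* the final excursion that never re-enters is a **departure** from its
  first day beyond threshold;
* within post-departure data, plateau days become **transient home range**
  (< 183 days) or **established** (≥ 183 days, including a plateau still
  ongoing at collar drop). "Six months" is fixed at 183 days.

The plateau test is a sliding 21-day window on NSD with coefficient of
variation ≤ 0.15 ("flat on the scale of the displacement itself"). A
centered window necessarily misses half a window at each plateau edge, so
windows only seed *core* days; each core run is then extended outward while
the adjacent day stays within 2× the CV tolerance of the core mean. That
two-stage rule is what keeps change-point errors near ±1–2 days rather
than ±10. Ambiguities resolve by the precedence natal > plateau > travel;
in particular a plateau *inside* a returning excursion stays exploratory —
only post-departure plateaus become transient ranges.

These thresholds are the operational translation of shape definitions that
are, in field practice, applied by eye to NSD plots; none is printed in the
literature as a number. They are all exposed in `segmentation_params()` and
were chosen once so that the three canonical NSD shapes separate cleanly on
simulated trajectories; raising `return_threshold` can only grow natal
coverage and delay departure, never the reverse (a property the tests
check).

**Multiple excursions** per animal are allowed, and per-state summaries
report both cumulative path length and straight-line displacement, since
reporting conventions differ by state.

## Covariates

Distance-to layers use an exact Euclidean distance transform
(two-pass lower-envelope algorithm, cell-center to cell-center), verified
against the brute-force all-pairs oracle to machine identity. Distances are
logged as `ln(d + cell/2)` — 15 m on a 30 m grid — so the transform is
defined on-feature and scale-aware; beyond ~100 cell-widths it is within 1%
of `ln d`. The terrain ruggedness index is the Riley root-sum-of-squares of
the 8 neighbor differences, translation-invariant, with edge cells using
the neighbors that exist. A class with no cells on the landscape yields a
sentinel-filled layer flagged degenerate and excluded from model
assembly.

Extraction is nearest-cell, never interpolated: distance layers are
piecewise and interpolation would blur the on-feature zero. Covariates are
z-scored with the stack's stored grid-wide mean/SD so coefficients are
comparable across layers and sites; standardization status travels with the
stack.

Collinearity screening computes Pearson correlations at sampled points and,
while any pair exceeds |r| = .60, drops the member of the worst pair with
the larger mean absolute correlation against the remaining layers (ties
alphabetically) — deterministic, and it removes the shared driver of a
correlated chain rather than its satellites.

## The estimator

**Tentative kernels.** Gamma step-length parameters by maximum likelihood
(`MASS::fitdistr`, method-of-moments fallback); zero step lengths are
replaced by 2.5 m — half the 5 m GPS precision floor — so the gamma support
is respected. Von Mises concentration by maximum likelihood with the mean
direction fixed at 0, solving `I₁(κ)/I₀(κ) = mean(cos ta)` with scaled
Bessel functions (negative mean cosine gives κ = 0).

**Strata.** Each used step with a defined turning angle anchors a stratum
of 20 random steps sharing its start point and time, lengths from the gamma
kernel and angles from the von Mises kernel applied to the incoming
bearing. The first step of a burst has no incoming bearing and is dropped —
simpler than a ta-free submodel and unbiased. Strata with any missing
covariate (off-raster endpoint) are dropped whole, a decision that depends
only on the proposal draws and is therefore ignorable for the conditional
likelihood.

**Fitting.** The conditional (matched-stratum) logistic log-likelihood
`Σ_s [η_used − ln Σ_j exp(η_j)]` is maximized by Newton–Raphson with the
analytic gradient and Hessian, step-halving, and convergence at gradient
∞-norm < 1e-8 — deterministic given the data. Standard errors come from the
inverse observed information; the implementation agrees with
`survival::clogit` to machine precision and with a derivative-free
hierarchical grid search to < 1e-4 (the tests keep both cross-checks).
Columns without within-stratum contrast and rank-deficient columns are
dropped with a warning. Complete separation — a coefficient running away —
flags the fit non-converged with infinite-SE sentinels, and such fits are
excluded from pooling. Individuals contribute only if they have at least
30 complete strata in the state.

Movement terms enter as `ln(sl)` and `cos(ta)` (matching the gamma shape
and von Mises concentration adjustments; an `sl` term for the scale
adjustment is supported and off by default, with the choice recorded in the
spec object). Interactions couple the movement terms with *start-point*
anthropogenic covariates — habitat at the start of a step modifies how the
animal moves, habitat at the end is what it selects.

**Kernel update and log-RSS.** The fitted movement coefficients update the
tentative kernels (`shape′ = shape + β_log_sl`, `1/scale′ = 1/scale −
β_sl`, `κ′ = κ + β_cos_ta`); updates leaving the valid domain are flagged.
Log relative selection strength between two habitat rows is `β·(x₁ − x₂)`
with a delta-method interval from the fit covariance.

**Pooling.** Fixed-effect inverse variance: `β̄ = Σ wᵢβᵢ / Σ wᵢ`,
`w = 1/se²`, `se̅ = (Σ w)^(−1/2)`, 95% normal CIs, significance = CI
excluding zero, and no multiple-testing correction (none is applied in this
analysis tradition; the output notes it). Cochran's Q and I² are reported
for information only. The two-site table marks terms significant at both
sites.

## The synthetic generator

The generator emulates what matters to the pipeline: 4-h (or faster) fix
schedules with Gaussian timestamp jitter and dropped fixes; scheduled
movement states (so ground-truth change points are exact, a deliberate
choice over emergent switching); gamma/von Mises movement kernels;
habitat-biased candidate choice (`n_candidates` draws, one chosen with
probability ∝ exp(β·z) plus a state-dependent attraction term that keeps
home-ranging animals near their center and produces the NSD plateaus);
and stationary kill-site clusters injected with schedule-respecting
timestamps. Landscapes are Poisson-placed disc patches per cover class,
1-cell road transects, and a sum of low-frequency sinusoids for elevation —
simple, seedable, and sufficient to create the covariate gradients the
estimator needs.

What it does **not** emulate: GPS positional error, terrain-dependent fix
failure, real land-cover geometry (NLCD class semantics, hydrology),
emergent behavioral switching, prey dynamics, or inter-individual
heterogeneity in selection. Passing validation therefore demonstrates that
the estimation chain is correct and well calibrated *under its own model
class*, not that field data meet those assumptions.

Two generator choices deserve emphasis because they were made after
explicit measurement, and are design decisions of the validation suite:

* **Generative candidate count.** The finite candidate set is a
  discretization of the continuous habitat-tilted choice model that
  conditional logistic regression estimates. Choosing among only 20
  candidates produces a measurably coarser process — selection coefficients
  attenuate by roughly 4% — while the *estimation* side, matching 20 random
  steps per used step, is part of the method under test. The validation
  experiments therefore simulate with 100 candidates (attenuation below
  Monte-Carlo error) and estimate with 20. `simulate_track()` itself
  defaults to 20 so the generative and inferential step sets stay
  comparable when users mirror an analysis.
* **Periodic landscapes for estimator validation.** A bounded walk needs a
  containment mechanism, and any containment term (attraction to a center)
  is an unmodeled within-stratum weight that leaks bias into covariates
  correlated with it — measurable as a slightly inflated false-positive
  rate under β = 0. The recovery, power, and null-calibration experiments
  therefore run free-roaming walks on a periodic (toroidal) landscape
  (`wrap = TRUE`), where no boundary and no containment exist and the
  generative model is exactly the fitted model class. The
  dispersal-geometry simulations (segmentation) keep bounded landscapes
  and the attraction mechanism, because there the NSD geometry is the
  point; the attraction model is a stand-in for natal residency, about
  which the movement literature specifies no generative form.

## Validation experiments and problem sizes

All sizes below are the package's own choices, stated here so results are
interpretable:

* **Recovery** (`run_recovery_experiment`): 100 replicates of a 10-animal
  site, 300 strata each, truth `(dist_forest_log, tri, dist_developed_log)
  = (−0.5, +0.25, +0.3)`, on a 24 km / 100 m-cell landscape. Reports bias,
  per-replicate 2-pooled-SE checks, and empirical CI coverage pooled over
  the three terms (300 interval checks; per-term n = 100 coverage is too
  granular to sit stably inside a ±2-percentage-point band).
* **Two-site power** (`run_twosite_power`): 50 replicates; site A has
  `dist_developed_log = +0.4`, site B `0`, all else equal; success is
  A-significant and B-non-significant.
* **Null calibration** (`run_null_calibration`): 200 single-animal
  replicates at β = 0, 150 strata; Wald 95% significance rates per term.
* **Permutation null** (`run_permutation_null`): 200 within-stratum
  shuffles of the used label on a strongly selected dataset; coefficients
  must center on zero.
* **Segmentation recovery** (`run_segmentation_experiment`): 20 animals on
  a 90 km / 300 m-cell landscape, schedule natal 35 d → exploratory 12 d →
  natal 14 d → departure 11 d → transient 60 d, waypoint and settlement
  distances (21 km, 40 km) sized to the walk's measured ~3.5–4 km/day
  directed-travel speed so states are as long as the travel they contain.

Coarser cells (100–300 m) than the 30 m analysis grid keep the distance
transforms and long walks light; the estimator sees covariate gradients,
not grid resolution, so nothing in the validation logic depends on cell
size.

## Numerical choices and degenerate inputs

* Distance transform: exact squared-distance lower envelope; sentinel +
  degenerate flag for absent classes; oracle-tested to zero deviation.
* Conditional likelihood: per-stratum max subtraction before
  exponentiation; uniform-stratum fast path; ridge of 1e-10 on the Hessian
  solve only as a safeguard.
* Grid-search oracle: hierarchical refinement down to step 1e-5 in a
  [−8, 8] box; the comparison is defined only where a finite interior
  optimum exists, so completely separated toy draws are regenerated.
* Von Mises sampling by the Best–Fisher rejection method; κ = 0 short
  circuits to uniform.
* Kernel MLE: `fitdistr` failures fall back to method-of-moments; κ is
  capped at 1e5 (numerically "straight ahead").
* Ties at the natal threshold resolve to natal; all run-length operations
  are on observed days, with calendar spans used for duration rules.

## Known limitations

* Fixed-effect pooling assumes homogeneous selection across individuals
  within a site; heterogeneity is reported (Q, I²) but not modeled. A
  random-effects or mixed-model step-selection formulation is out of scope.
* The segmentation classifier is threshold-based, not a formal change-point
  model competition; its accuracy guarantees hold under the generator's
  movement scales and would need re-examination for very slow dispersers
  or very gappy collars.
* Model-based SEs are used per individual; with strong spatial
  autocorrelation and misspecified movement kernels they can be mildly
  anti-conservative, which is visible only as small excesses over the
  nominal 5% in the null calibration.
* No DOP/accuracy screening of fixes is applied, and positional error is
  not part of the generator.
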