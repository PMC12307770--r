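---
title: "Methods: from swim tracks to behavioral endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from swim tracks to behavioral endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimmaze)
```

This vignette documents the models and conventions behind each analysis
stage, the parameters that matter, and the choices made where the underlying
definitions were genuinely open.

## Arenas, zone assignment, and visit extraction

An arena is a flat 2-D description of a tank: named zones (rectangles,
circles, annuli, polygons; mm; origin at the lower-left), an adjacency graph
of traversable boundaries, and role labels (`"shallow_arm"`, `"center"`,
`"stimulus"`, ...). The six presets carry the published tank dimensions:
slalom 20 × 85 mm in 12 chambers, SPM arms 8 × 10 mm around an 8 × 8 mm
center, SJ 42 mm in 4 chambers, OT wells of 35 mm diameter, and Y-maze arms
7.5 × 30 mm at 120°. The OT's aversive central circle covers 80% of the
arena area by construction, i.e. a radius ratio of exactly √0.8 — this is
validated to 1e-9 whenever an OT arena is built. The sociability lane ships
with schematic dimensions (its exact tank is not standardised); its role
structure — stimulus / intersection / no-stimulus — is what the endpoints
consume.

*Assignment convention.* A frame belongs to the zone containing the
animal's center point. Trackers differ in whether they report center-of-mass
or head position; the center point is the most common export and is used
throughout (a flagged convention, not a finding). Boundaries are inclusive
and a point on a shared edge goes to the first zone in declaration order —
this makes all shared edges half-open in a single, auditable way (the SPM
declares its center first, so arm/center edges belong to the center).
Samples in no zone are labelled `"none"`.

*Visit extraction.* Runs of identical labels become visits. `"none"` runs
are absorbed into the preceding visit (a tracking dropout does not end a
visit); leading `"none"` runs have no preceding visit and are dropped, and
the session length used for conservation checks and censoring is the span
covered by the visits. Runs shorter than `min_dwell` are merged into a
flanking visit, shortest first, with the preceding visit preferred when the
flanks differ. The default `min_dwell = 0.2` s (≈ 6 frames at the 30 fps
video convention) suppresses single-frame boundary flicker; 0 disables
de-bouncing. Increasing `min_dwell` can only merge visits, never split them,
so visit counts are monotone non-increasing in the threshold (tested as a
property).

*Session metrics.* Entries are visit counts; first-entry latency for a
never-entered zone is censored at the session length and flagged. Mean
velocity is whole-session path length over elapsed time, immobile periods
included (whether trackers exclude immobile frames varies; the whole-session
convention is the simpler and is stated). An immobile episode is a maximal
run of inter-frame speed below 1 mm/s lasting at least 1 s — both thresholds
configurable, since "immobility" has no universal definition at this body
size.

## Population-scaled endpoints

Min-max scaling across the analysed population underlies both headline
endpoints. The *batch* being scaled is an explicit analysis decision: all
subjects meant to be compared on one axis (typically one species × one
experiment) must be scaled together, and cross-group contrasts must pool the
groups into one batch before scaling — scaling each group against itself
erases the group difference. A column with zero range scales to 0 for every
subject (rather than NaN) so averages over chambers stay defined;
consequently a batch in which nobody entered a chamber contributes 0 for
that chamber.

- **Mean transition latency**: per-chamber first-entry latencies (censored
  at the session length), min-max scaled per chamber across the batch, then
  averaged over chambers within subject; MTL ∈ [0, 1].
- **Anxiety score**: `scaled(shallow latency) − scaled(shallow time)`. The
  defining phrase "scaled time minus scaled latency multiplied with −1" is
  ambiguous about operator binding; the reading adopted here is the only one
  that is *positively* oriented with avoidance (long latency and little time
  in the aversive arm ⇒ high score), which is the stated intent of the
  endpoint. Range [−1, 1].

Both endpoints are invariant to common affine rescaling of the raw variable
across the batch (tested as a property).

## Y-maze action classification

Arm visits are scored in a sliding window of three consecutive visits; every
window receives exactly one label. Precedence is direct revisit >
alternation > indirect revisit: the action definitions name direct revisits
on *pairs* but report a three-way distribution over *triads*, so a triad
containing any immediate repeat is counted as a direct revisit, and the
remaining triads split into alternations (three distinct arms) and indirect
revisits (A→B→A). Pairwise repeat counts are additionally exported for
transparency. The denominator of alternation% is the number of windows
(length − 2), the rodent-literature convention that puts uniform no-stay
random choice at 50% and a perfect alternator at 100%. Arm sequences derived
from zone visits absorb the center zone: passing through the center does not
end an arm visit, only arrival at a different arm does.

## Repeatability

The endpoint model is a one-way random-intercept decomposition
`y_ij = μ + b_i + e_ij` (subject i, session j). Repeatability is the
intraclass correlation R = σ²_b / (σ²_b + σ²_e) — the between-subject share
of total variance. Variance components are estimated by the closed-form
ANOVA method of moments with the unbalanced-design coefficient
k0 = (N − Σn_i²/N)/(n − 1); negative between-subject estimates are truncated
at 0 before forming R, so R ∈ [0, 1]. The method-of-moments estimator is
hand-checkable and dependency-free; it coincides with the REML mixed-model
estimate on balanced designs with interior solutions (cross-checked against
`lme4` in the tests) and is documented as an approximation to the
mixed-model estimator otherwise. Covariate-adjusted ("adjusted")
repeatability is out of scope, noted as an extension point.

Confidence intervals are percentile intervals from a parametric bootstrap
(default 1000 replicates): each replicate simulates the fitted Gaussian
random-intercept model on the identical subject-session design and
re-estimates R. The significance rule is the conventional one for
repeatability: an estimate whose 95% CI excludes 0. Subjects with fewer than
two sessions carry no within-subject information and are dropped. SiM (the
single measure) takes session 1 — which session a single measurement "would
have been" is not derivable from the design, and session 1 is the only
choice that exists for every subject; SuM averages all available sessions.

## Mixture modality

`fit_gmm_1d()` is a standard EM for univariate Gaussian mixtures with free
component variances (an equal-variance flag switches the constraint and the
parameter count from 3K − 1 to 2K). Numerical choices: 10 restarts with
means initialised at jittered spread quantiles, equal weights, pooled-variance
initialisation; convergence when the log-likelihood gain falls below 1e-8 or
500 iterations; a variance floor of 1e-6 × sample variance preventing
degenerate spikes on repeated values; components reported sorted by mean.
The restart structure makes the fit deterministic under a seed. The EM
ascent property (log-likelihood non-decreasing every iteration) is asserted
in the tests. The kernel is compiled (Rcpp) because the modality decision
refits three model sizes with ten restarts each and is used inside
simulation sweeps.

BIC is reported in the higher-is-better orientation 2·loglik − p·ln n, the
convention of the mixture-modelling packages this analysis style comes from;
"highest BIC" then coherently selects the most supported component count.
The phrase "highest BIC absolute values" in the source analysis tradition is
read as the highest criterion value, not |BIC|. Scaled BIC is min-max over
the K grid per variable, so the best K shows 1 and the worst 0.

## Effect sizes

The standardized effect is |mean(a) − mean(b)| divided by the SD of the
pooled observations (n − 1 denominator) — "total standard deviation" is read
literally as the SD of the combined sample rather than the pooled
within-group SD of classical Cohen's d. The total-SD denominator includes
the group shift itself, so values are smaller than Cohen's d for the same
contrast; both denominators are exposed and the choice is recorded in the
result. Per-comparison pooling (not per-species) is used when several
populations enter one contrast. Composite effects are unweighted means of
component effects. No confidence intervals are attached — the summary is
descriptive, and inferential comparisons should use the exported tidy tables
with standard tests.

## The synthetic generator: what it does and does not emulate

The generator exists so that every analysis stage can be exercised against
known truth; its defaults are chosen for testability and are not calibrated
to any particular species.

- `simulate_visits()`: a continuous-time Markov walk on the zone graph —
  exponential dwell with per-zone means (default 5 s), next zone
  proportional to adjacency weights. Avoidance `a` multiplies aversive-zone
  dwell *and* entry weight by e^(−a), jointly producing shorter stays and
  longer first-entry latencies, which is exactly the signature the anxiety
  score integrates. Subjects get i.i.d. log-normal dwell-rate multipliers
  (SD on the log scale), optionally mixed over explorer components; this
  induces the between-subject variance that repeatability measures.
  Rendering to a 30 Hz track adds within-zone positional jitter constrained
  to the generating zone, so event recovery through
  `assign_zones() → extract_visits(min_dwell = 0)` is exact by construction.
- `simulate_ymaze()`: first two visits uniform distinct; then direct revisit
  with probability `p_direct`, otherwise alternation-completing arm with
  probability `p_alt`, otherwise return to the previous arm. `p_alt = 0.5,
  p_direct = 0` is the uniform no-stay policy with expected alternation%
  of exactly 50.
- `simulate_repeated()`: the Gaussian random-intercept model with true
  R = σ²_b/(σ²_b + σ²_e) attached, used for estimator calibration.
- `simulate_population_values()`: i.i.d. Gaussian-mixture draws for the
  modality analysis.

Determinism: every generator takes a mandatory seed; one master stream
derives stable per-subject sub-seeds, so per-subject output does not depend
on simulation order and identical configurations reproduce byte-identical
results.

What the generator does **not** emulate: biomechanics (no inertia, no
realistic speed profile beyond the rendering jitter), social interaction
between simulated animals (a companion condition can only be mimicked as a
rate shift), wall-following and thigmotaxis microstructure, habituation
within or across sessions, and any empirically fitted parameter values.
Passing tests therefore demonstrate that the *analysis* recovers the
structure the generator puts in — effect directions, variance ratios,
mixture separation — not that real fish behave like the generator.

## Problem sizes used by the test suite

The suite calibrates estimators at sizes chosen to make Monte-Carlo error
small relative to the asserted tolerances while keeping a full run around
half a minute: the repeatability grid uses true R ∈ {0.1, …, 0.9} with
n = 100 subjects × 3 sessions × 200 replicates (mean estimate within ±0.05
of truth); modality recovery uses 50 seeded runs of n = 300 at 8-SD
component separation (≥ 95% correct); the Y-maze random-choice null uses 32
subjects × 200 visits (mean alternation% within 2 points of 50); and the
avoidance-to-anxiety-score closure uses 3 × 50 subjects × 600 s sessions
scaled as one batch.

## Known limitations

- Geometry is strictly 2-D; depth-based zones (shallow vs deep arms) are
  encoded as labelled 2-D regions only.
- Zone interiors are assumed disjoint by construction of the presets; the
  declaration-order tie-break silently resolves any overlap a custom arena
  introduces.
- The ANOVA estimator can be biased for strongly unbalanced designs where a
  mixed-model (REML) estimator would pool better.
- The EM variance floor trades a small likelihood distortion for robustness
  on quantised endpoints.
- Min-max scaling makes MTL and the anxiety score batch-relative: values are
  not comparable across batches scaled separately, which is inherent to the
  endpoint definition, not an implementation choice.
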