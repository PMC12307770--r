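# swimmaze

Individual-based analysis of larval and juvenile fish behavior in swim-maze
assays: from zone-labelled swim tracks to population-scaled behavioral
endpoints, Y-maze action classification, behavioral-consistency statistics,
distribution-modality decisions, and standardized effect-size summaries.

The package targets researchers running small-arena exploration and anxiety
assays on individual fish (zebrafish, paradise fish and similar larval/juvenile
subjects) who track positions with video software and need a reproducible,
scripted path from tracking exports to the endpoints used in comparative
behavioral studies.

## What it computes

**Arenas and events.** Six built-in arena geometries (`arena_preset()`): a
12-chamber slalom maze, the swimming plus-maze (SPM; two shallow and two deep
arms around a center), a 4-chamber show-jump tank (SJ), a circular open tank
(OT) whose aversive central circle covers 80% of the area (radius ratio
√0.8), a 3-arm Y-maze, and a schematic sociability lane. Per-frame tracks are
labelled by zone (`assign_zones()`, center-point containment,
declaration-order tie-break), de-bounced into visit sequences
(`extract_visits()`), and summarised per session (`session_metrics()`: zone
times, entries, first-entry latencies with censoring, mean velocity,
immobile episodes).

**Endpoints.** For a population of subjects analysed as one batch:

- *Mean transition latency* (slalom/SJ): per-chamber entry latencies are
  min-max scaled across the population, then averaged over chambers within
  subject — MTL ∈ [0, 1], 0 = fastest explorer.
- *Anxiety score* (SPM): `scaled(latency) − scaled(time)` for the aversive
  shallow arms, i.e. `(scaled time − scaled latency) · (−1)` — in [−1, 1],
  higher = more avoidance.
- *Success rate*, *zone preference* (time% and entries by zone role).

**Y-maze actions.** Sliding window over arm visits: each consecutive triple
is an *alternation* (three distinct arms), *direct revisit* (an immediate
repeat), or *indirect revisit* (return to the arm before last);
`alternation_percent()` is 100·alternations/windows, with 50% the
random-choice reference under a uniform no-stay policy.

**Consistency.** Agreement repeatability R = σ²(between-subject) /
(σ²(between) + σ²(within)) from a one-way random-effects ANOVA decomposition,
with 95% CI by parametric bootstrap (default 1000 replicates) and the
CI-excludes-zero significance rule; single measures (SiM, session 1) vs
summary measures (SuM, session means) and Pearson/Spearman inter-test
correlations.

**Modality.** Univariate Gaussian-mixture fits (EM, compiled kernel) for
K = 1..3 components; the component count with the highest BIC
(2·loglik − p·ln n, higher is better) decides uni/bi/trimodality; BIC is also
min-max scaled to [0, 1] over the K grid for display.

**Effect sizes.** `|mean(a) − mean(b)| / sd(a ∪ b)` (total-SD standardisation;
classical pooled-within Cohen's d available as an option) and unweighted
composites across endpoints.

**Synthetic behavior.** A seeded generator used throughout the tests:
continuous-time Markov walks on the arena zone graph with exponential dwell
times, subject-level log-normal rate multipliers, an avoidance parameter that
scales aversive-zone dwell and entry by e^(−a), parameterized Y-maze choice
policies, random-intercept repeated measures with known true R, and Gaussian
mixture populations.

## Worked example

```r
library(swimmaze)

spm <- arena_preset("spm")
sim <- simulate_visits(spm, n_subjects = 12, session_length = 600,
                       avoidance = 2, aversive_roles = "shallow_arm",
                       subject_sd = 0.3, start_zone = "center", seed = 42)
sh <- zones_with_role(spm, "shallow_arm")
st <- vapply(sim$visits, function(v) {
  z <- session_metrics(v, NULL, spm)$zones
  c(time = sum(z$time_s[z$zone_id %in% sh]),
    lat  = min(z$latency_s[z$zone_id %in% sh]))
}, numeric(2))
round(head(anxiety_score(st["time", ], st["lat", ]), 4), 3)
#>   S001   S002   S003   S004
#> -0.980 -0.887 -0.266 -0.200

seqs <- simulate_ymaze(12, 60, p_alt = 0.7, p_direct = 0.05, seed = 42)
classify_actions(seqs[[1]])
#> <action_counts> windows: 58 | alternations: 37 | direct: 6 | indirect: 15

m <- simulate_repeated(10, sd_between = 1, sd_within = 1,
                       n_subjects = 40, k_sessions = 3, seed = 42)
repeatability(m, n_boot = 1000, seed = 42)
#> <repeatability_estimate> R = 0.675  95% CI [0.487, 0.785]  (significant)
#>   var between-subject = 1.622, within-subject = 0.7808, n = 40, n_boot = 1000

x <- simulate_population_values(c(0.5, 0.5), c(0.2, 0.7), c(0.08, 0.08),
                                n = 120, seed = 42)
select_modality(x, seed = 42)
#> <modality_decision> best K = 2
#>  K     BIC scaled
#>  1 -21.196  0.000
#>  2 105.074  1.000
#>  3  98.886  0.951
```

The anxiety scores are relative to the analysed batch (−1 = the batch's most
exploratory subject, +1 = its strongest avoider); subject S001 explores the
shallow arms most readily. The Y-maze subject alternated in 37 of 58 windows
(63.8%), above the 50% random-choice line. The repeated-measures example has
true R = 0.5; the estimate 0.675 carries a bootstrap CI that excludes 0, so
the endpoint counts as repeatable. The mixture example is generated bimodal
and K = 2 wins the BIC comparison.

`run_pipeline(list(seed = 1), "out/")` chains all stages on synthetic data
and writes tidy CSV/JSON outputs plus a manifest; rerunning with the same
configuration reproduces every file byte-identically.

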