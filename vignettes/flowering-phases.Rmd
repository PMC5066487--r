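---
title: "Segmenting longitudinal flowering series into stationary phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting longitudinal flowering series into stationary phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flophase)
```

## The model

Weekly counts of newly emerged inflorescences on the plants of one genotype
are treated as a single multivariate series `x = x_1, ..., x_T`: one
variable per plant, one index per measurement week. The working assumption
is that the flowering pattern is *piecewise stationary and synchronous*:
there exist `J - 1` change points `tau_1 < ... < tau_{J-1}` shared by all
plants of the genotype, and within each of the `J` resulting phases the
weekly count of every plant is an independent draw from a phase-specific
categorical distribution `theta_j`.

Counts are encoded on the support `0..5` (`encode_counts()`, `cap = 5`):
weekly counts of five or more are pooled into the top category because they
are too rare for their masses to be estimated separately, while panels of
around thirty plants times several weeks per phase are ample for direct ML
estimation of six masses. Phase mean counts are always reported from the
*uncapped* values, so the capping only affects the likelihood, not the
descriptive summaries.

A segmentation `s` is scored by its **profile log-likelihood**: each
segment `u..v` contributes `sum_c n_c log(n_c / n)` where `n_c` counts
category `c` among the `P * (v - u + 1)` pooled observations
(`segment_cost()`). Every candidate segmentation is thus evaluated at its
own per-segment ML frequencies. This plug-in convention makes the sum over
segmentations below well defined, and it matches how the within-phase
distributions are actually estimated once a segmentation is chosen.

The engine computes, exactly:

* `optimal_segmentation()` — the DP argmax over all segmentations,
  `O(T^2 J)` segment evaluations;
* `log_marginal()` — `log L_J(x) = log sum_s L_J(s, x; theta-hat)` over all
  `choose(T-1, J-1)` segmentations, by a forward recursion in log-space;
* `segmentation_entropy()` — the Shannon entropy of the posterior over
  segmentations, via the decomposition `H = log L_J(x) - E[score(S)]`,
  where the expectation is taken under the exact posterior weights of
  "phase j spans u..v" obtained from the forward and backward log-sums;
* `icl()` — the integrated completed likelihood
  `ICL_J = 2 log L_J(x) - d_J log T - 2 H(S | X = x; J)`;
* `model_posteriors()` — `P(M_J | x) ∝ exp(ICL_J / 2)` over `J = 1..Jmax`;
* `segmentation_posterior()`, `top_segmentations()`,
  `posterior_profiles()` — the weight of the optimum among its rivals, the
  ranked N-best list, and the smoothed occupancy / phase-entry probability
  grids used to visualise change-point uncertainty.

The ICL's entropy term is what distinguishes it from BIC-style criteria: it
additionally penalises models whose segmentation is ambiguous, which is the
right notion of complexity when the segmentation itself — not merely the
fit — is the object of interest.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cap` | 5 | count | six categories; values >= 5 are individually rare |
| `Jmax` | 6 | phases | generous upper bound for a 28-week season |
| `d` (free parameters) | `(J-1) + J(C-1)` | — | interior change points plus `C-1` masses per phase |
| `penalty` | `log T` | nats | the criterion as written; `log(PT)` available via `penalty = "logPT"` |
| `min_phase_weeks` | 2 | weeks | 1-week phases read as plant asynchronism |
| `ambiguity_ratio` | 0.5 | — | rival posterior at least half the best |
| `ambiguity_shift` | 3 | weeks | rival must move a change point materially |
| `late_mean_threshold` | 1.3 | count/week | separates late means ~0.9-1.1 from ~1.4-1.9 |

The free-parameter count `d_J` and the `log T` penalty deserve comment,
because for this model family both admit alternatives. We count the
`J - 1` change points as free parameters alongside the `J (C - 1)`
category masses; and we penalise with the log of the number of measurement
dates `T`, not of the cumulative sample size `P * T`, because the change
points live on the time axis — only more *dates* add resolution for them.
Both choices are exposed (`d`, `penalty`) so users can explore the
alternatives; the defaults are used throughout the tests.

## The selection policy

For series as short as 28 weeks the ICL-preferred `J` is indicative rather
than definitive, and published analyses of such data apply case-by-case
downgrades. `select_num_phases()` codifies them deterministically:

1. **Short phases.** While the optimal segmentation at the current `J`
   contains a phase shorter than `min_phase_weeks`, refit with `J - 1`
   phases and flag `one_week_phase`. Refitting (rather than literally
   merging the short phase into a neighbour) needs no adjacency choice and
   stays within the DP framework; the result is the optimal segmentation
   at the reduced `J`, which is what is wanted for genotype comparison.
2. **Ambiguity.** If at the resulting `J` the second-best segmentation has
   posterior at least `ambiguity_ratio` times the best *and* displaces a
   change point by at least `ambiguity_shift` weeks, the phase structure is
   not trustworthy at that resolution: flag `ambiguous` and drop one more
   phase. The thresholds are one operationalisation of "two markedly
   different alternative segmentations"; they are policy parameters, not
   estimates.

Both the ICL-preferred and the selected `J` are retained, so the automated
path is auditable against manual judgment. `classify_genotypes()` then
groups genotypes: `ambiguous` ones are `intermediate`; four-phase fits
whose final phase stays below `late_mean_threshold` (1.3 weekly
inflorescences, midway between the ~1.1 "refinement" late means and the
1.4-1.9 genuinely intense ones) count as three-phase patterns whose
perpetual-flowering phase was merely split.

`consensus_segmentation()` stacks the plants of a genotype group into one
series (the profile likelihood pools category counts, so this is the
natural multi-genotype extension) and segments it once; the resulting
phase windows feed `phase_trait_table()`, whose per-plant, per-phase
cumulative counts are the traits used in marker tests.

## Association statistics

The downstream tests are deliberately standard and delegate to base R:
Spearman/Pearson correlations (`stats::cor.test`) between inflorescence
and stolon emergence rates at the sparse stolon dates
(`rate_correlation()`, with `to_rates()` converting unevenly spaced counts
to weekly rates), a pooled-variance Student's *t* (`stats::t.test`) for
the marker contrast with the difference oriented `mean(A) - mean(H)`
(`marker_effect_test()`; Welch available via `var_equal = FALSE` since
variances plausibly differ between marker classes), one-way ANOVA
(`stats::aov`) across genotypes (`group_mean_anova()`), and end-of-season
organ summaries (`season_summary()`). Correlations default to pairing
per-date means over plants, which is how pooled rate profiles are usually
displayed; `level = "plant"` pairs every plant-date observation instead.

## The synthetic generator

No raw per-plant series are publicly available for this kind of study, so
`synthetic_config()` / `sample_study()` generate panels with exactly the
structure the model assumes, anchored to published summary values:

* 28 weekly dates (weeks 16-43), 30 plants per genotype by default;
* three-phase genotypes switch at weeks 19|20 and 24|25 with phase means
  0.45 / 0.10 / 0.92; four-phase genotypes at 18|19, 24|25, 30|31 with
  means 0.45 / 0.10 / 0.92 / 1.65; seasonal genotypes flower only in the
  first phase;
* within-phase counts are i.i.d. draws on the raw support 0..8 (so the
  downstream capping rule is actually exercised) from truncated-Poisson
  shapes solved to hit the phase means exactly — right-skewed with mode 0
  (means < 1) or 1, matching the reported within-phase histogram shapes;
* the marker is concordant with the pattern (absence A with four-phase,
  presence H with three-phase) with probability `penetrance` (default 1;
  lower values reproduce the occasional discordant genotype);
* stolon counts are Poisson with propensity
  `max(0, budget - weekly inflorescence count) * scale(habit)`, thinned to
  the sparse stolon dates (19, 21, 23, 26, 29, 32, 35, 39, 43). The budget
  (2.5) and habit scales (PF 0.15, SF 0.45) were chosen once so that
  season stolon totals land near the published group means (~6.5 for PF,
  ~30 for SF) and flowering-runnering coupling is negative by
  construction;
* crowns are Poisson at class means 3.8 / 6.7 / 4.6, giving cumulative
  (inflorescences + stolons + crowns) season totals near the published
  pooled group means (~29-30 versus ~42).

What the generator does **not** emulate: between-plant change-point
asynchronism beyond the optional ±1-week jitter (off by default), serial
correlation of counts within a plant (an AR-style carryover is a stress
knob, also off by default), environment-driven synchronous fluctuations
within phases, and plant death / missing weeks. Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions and calibrated effect sizes — not robustness to every feature
of real field data.

## Numerical choices and degenerate inputs

* All likelihood sums use log-space accumulation (`logsumexp`), so panels
  of hundreds of plants over a hundred weeks stay finite.
* DP ties are resolved towards the smallest segment-start index at each
  backtracking step; a constant series deterministically yields change
  points `2, 3, ..., J`.
* `0 log 0 = 0` throughout; entropies are clamped at 0 against roundoff.
* The entropy has two independent implementations — the forward-backward
  decomposition and explicit enumeration — tested against each other; the
  smoothing path is the default since enumeration is infeasible beyond
  small `T`.
* Degenerate inputs degrade explicitly: constant series give `rho = 0`
  with a warning (or an error, per `on_constant`), zero-variance marker
  groups report the mean shift with `t = NA` and a warning, an all-equal
  ANOVA reports `F = 0` with a warning.
* Plants with missing weeks are dropped at load time, not imputed:
  imputation would distort the within-phase category frequencies that the
  whole likelihood rests on. The first interval of a rate series defaults
  to one elapsed week when no baseline is given; any constant baseline
  only rescales that single point.

## Problem sizes in the test battery

The exhaustive-enumeration oracle checks run on 200 randomised panels with
`T <= 10`, `J <= 4`, `P <= 3`; change-point recovery and model selection
are measured over 100 seeded panels at the default study conditions
(`P = 30`, `T = 28`); the marker pipeline is replicated 50 times with 10
genotypes per replicate; consensus pooling uses 8 genotypes (240 plants).
These sizes give stable rates while keeping the full suite fast.

## Interface note

The package's surface is its exported functions plus
`scripts/acceptance.R`; the analysis it implements is naturally driven
from R scripts and this vignette rather than a shell command-line, so no
separate CLI binary is shipped.

## Known limitations

* Change points are strictly synchronous within a genotype; per-plant
  change points are out of scope.
* Only categorical emissions are provided (no Gaussian/Poisson segment
  models) — for capped count data they are the right tool, and they keep
  every computation exact.
* The ambiguity thresholds are a policy, not an inference; genuinely
  borderline genotypes should be inspected via `top_segmentations()` and
  `posterior_profiles()`.
* Linkage maps, interval mapping and LOD-based QTL scans are out of scope;
  marker association here is single-marker only.
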