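# flophase

Segmentation of longitudinal flowering series into stationary phases, with
downstream marker-association statistics.

## The problem

Perpetual-flowering (PF) strawberry genotypes do not flower at a constant
rate: weekly counts of newly emerged inflorescences switch abruptly between
a small number of stationary regimes over the growing season — a spring
flush of autumn-initiated inflorescences, a pause, then one or two
perpetual-flowering phases of increasing intensity. Characterising these
phases, deciding how many there are, and locating the weeks at which a
genotype switches phase is a prerequisite for any genetic analysis of the
flowering pattern: phase-specific trait values (e.g. inflorescences emerged
during the late intense phase) are what single-marker tests and QTL scans
operate on.

`flophase` is aimed at plant phenotyping analysts working with weekly (or
otherwise regular) organ-emergence counts recorded on many plants per
genotype, where the phase structure can be assumed synchronous across the
plants of a genotype.

## The model

All `P` plants of a genotype observed over `T` weeks form one multivariate
series. A *synchronous multiple change-point model* with `J` phases places
`J − 1` interior change points `τ₁ < … < τ_{J−1}`, and within phase `j`
treats every weekly count of every plant as an i.i.d. draw from a
categorical distribution `θⱼ` over the capped support `{0, 1, …, 5}`
(counts ≥ 5 are pooled — they are too rare for separate mass estimates).

A segmentation `s` is scored by its profile log-likelihood: each phase uses
its own ML category frequencies, pooled over plants and weeks. On top of
this the package computes, exactly:

* the optimal segmentation `s* = argmax_s log L_J(s, x; θ̂)` by dynamic
  programming (`O(T²J)`);
* the likelihood summed over all `choose(T−1, J−1)` segmentations,
  `L_J(x) = Σ_s L_J(s, x; θ̂)`, by a forward recursion in log-space;
* the entropy `H(S | X = x; J)` of the posterior over segmentations, by a
  forward–backward decomposition;
* the model-selection criterion
  `ICL_J = 2 log L_J(x) − d_J log T − 2 H(S | X = x; J)`,
  with `d_J = (J − 1) + J(C − 1)` free parameters, and the model posteriors
  `P(M_J | x) ∝ exp(ICL_J / 2)`;
* the posterior `P(s* | x; J)`, the top-`N` most probable segmentations,
  and smoothed profiles `P(S_t = j | x)` / `P(S_t = j, S_{t−1} = j−1 | x)`
  for change-point uncertainty.

A selection policy layer turns the ICL value (indicative only for short
series) into a reported number of phases: models whose optimum contains a
phase shorter than 2 weeks, or two nearly equiprobable but markedly
different segmentations, are downgraded to one phase fewer. Genotypes are
then grouped into three-phase / four-phase / intermediate flowering
patterns, pooled into consensus segmentations, and phase-specific traits
are tested against marker presence with Student's *t*; flowering–runnering
coupling is measured with Spearman rank correlations on emergence rates.

A seeded generator (`synthetic_config()`, `sample_study()`) emulates the
panel structure: 28 weekly dates (weeks 16–43), ~30 plants per genotype,
right-skewed within-phase count distributions with means ≈ 0.45 / 0.10 /
0.92 / 1.65, a binary marker whose absence turns on the late intense
phase, and stolon counts negatively coupled to flowering through a shared
budget.

## Worked example

```r
library(flophase)

cfg   <- synthetic_config(n_genotypes = c(three_phase = 1, four_phase = 1), seed = 42)
study <- sample_study(cfg)

cs <- encode_counts(study$panels$FP_01)     # cap counts at 5 -> 6 categories
segment_series(cs, Jmax = 6)
#> <segmentation_report> FP_01 (ICL prefers J = 4)
#>  J      ICL log_marginal entropy P_model P_opt_seg
#>  1 -2313.09     -1148.21   0.000   0.000     1.000
#>  2 -2032.01      -997.32   0.362   0.000     0.896
#>  3 -2001.06      -971.54   0.665   0.001     0.702
#>  4 -1987.84      -954.22   1.377   0.996     0.465
#>  5 -1999.75      -947.83   3.732   0.003     0.124
#>  6 -2012.28      -942.33   5.499   0.000     0.065
```

The ICL criterion prefers four phases with model posterior 0.996; the
optimal four-phase segmentation carries 0.465 of the posterior mass over
all 2925 four-phase segmentations. The policy layer confirms it and
reports calendar-week limits with uncapped phase means:

```r
select_num_phases(cs)
#> <genotype_classification> FP_01: selected J = 4 (ICL J = 4)
#>  phase first_week last_week length_weeks mean_weekly_count
#>      1         16        18            3             0.456
#>      2         19        24            6             0.089
#>      3         25        30            6             0.894
#>      4         31        43           13             1.646
#> posterior of segmentation 0.465, of model 0.996
```

(The generating truth was phases 16–18 / 19–24 / 25–30 / 31–43 with means
0.45 / 0.10 / 0.92 / 1.65 — every change point is recovered exactly here.)
Pooling both genotypes and testing the late-phase trait against the marker:

```r
cons <- consensus_segmentation(lapply(study$panels, encode_counts), 4)
tt   <- phase_trait_table(study$panels, cons$segmentation)
marker_effect_test(data.frame(genotype = tt$genotype, value = tt$phase4),
                   study$markers, "EMFv020_146")
#> <marker_effect> EMFv020_146: mean(A) = 22.63 (n=30), mean(H) = 11.97 (n=30),
#>   A-H = 10.67, t = 9.02, p = 1.25e-12
```

Plants of the genotype lacking the marker (state A) produced ~10.7 more
inflorescences during the late phase than carriers — the expected effect of
a 13-week phase at mean 1.65 versus 0.92 per week.

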