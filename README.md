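# choosyn

Selecting the number of muscle synergies from surface EMG of cyclic
locomotion.

## The problem

Muscle synergy analysis models preprocessed multi-muscle sEMG envelopes
`V` (muscles × time) as a non-negative factorization

```
V ≈ W C,    W ∈ R^{m×n}_{≥0},  C ∈ R^{n×T}_{≥0}
```

where the columns of `W` are weight vectors (the time-invariant loading of
each muscle on a synergy) and the rows of `C` are activation coefficients
(each synergy's drive across the gait cycle). The factorization needs the
number of synergies `n` as an input, and `n` is itself used as a marker of
neuromuscular complexity — so choosing it well matters. The classical
recipe thresholds the variance accounted for,

```
VAF = (1 − Σ(V − WC)² / ΣV²) × 100 ,
```

at an arbitrary 90% or 95%. This package implements **ChoOSyn**, a
threshold-free criterion built on two principles: synergies should be
*consistent across time* (stable across 10-cycle epochs of the walk) and
*mutually dissimilar* (an information-rich base without redundancy). For
each candidate order `n = 2..8` it computes

```
ChoOSynW(n) = WS(n) + ICVW(n)        ChoOSynC(n) = CS(n) + ICVC(n)
```

where ICVW/ICVC are worst-case intra-cluster variabilities of weights and
coefficients across epochs (`max_i (1 − mean_j cos(member_ij, centroid_i))`),
WS is the worst-case pairwise cosine between weight centroids, and CS is
the cosine between the two activation centroids born from splitting one
level-(n−1) synergy. Steps and local minima of these profiles locate the
optimal order. The package also provides the three VAF baselines (T-VAF
90/95%, elbow E-VAF, plateau P-VAF), the full extraction pipeline
(segmentation, 35 Hz/12 Hz Butterworth envelopes, amplitude normalization,
10-cycle subgroups, NMF/ANLS, cosine k-means sorting), a pseudo-real sEMG
simulator with known ground truth, and a benchmark harness scoring every
criterion by fraction correct, mean error and RMSE.

## Worked example

Simulate one 5-minute-style walk with 5 known synergies, run the pipeline,
and ask every criterion for the number of synergies:

```r
library(choosyn)

gt  <- generate_ground_truth(true_n = 5, m = 12, n_cycles = 31, seed = 7)
rec <- synthesize_emg(gt, snr_db = NA, carrier_seed = 1, noise_seed = 2)

subs  <- preprocess_emg(rec)                        # 3 ten-cycle subgroups
extr  <- extract_synergies(subs, n_range = 1:8, seed = 3, reruns = 3)
curve <- vaf_curve(extr)
tidy(curve)
#> # A tibble: 8 × 2
#>       n   vaf
#>   <int> <dbl>
#> 1     1  33.6
#> 2     2  55.9
#> 3     3  73.9
#> 4     4  88.0
#> 5     5  99.3
#> 6     6  99.4
#> 7     7  99.6
#> 8     8  99.7

select_tvaf(curve, 90)   # first VAF ≥ 90%  -> 5
select_evaf(curve)       # elbow            -> 5
select_pvaf(curve)       # plateau          -> 5

profile <- build_profile(build_synergy_stack(extr, seed = 4))
select_n_choosyn(profile)
#> <choosyn_selection> n = 5 (rule: common)
```

The VAF curve climbs steeply while real structure is being added, saturates
at the true order (99.3% at n = 5; only carrier ripple remains), and the
ChoOSyn profiles step up right after it — both weight and coefficient sides
nominate n = 5, so the common-candidate rule fires. `autoplot()` methods
draw the VAF curve, the ChoOSyn bar profiles and benchmark summaries;
`tidy()`/`glance()` return tibbles.

The full simulation study is one call each:

```r
ds    <- build_simulated_dataset(dataset_config_desk(snr_db = NA), seed = 42)
bench <- run_benchmark(ds, methods = c("evaf", "pvaf", "choosyn"),
                       reruns = 3, seed = 42)
glance(bench)
```

A thin CLI wrapping these functions lives at `inst/cli/choosyn.R`
(subcommands `simulate`, `extract`, `select`, `benchmark`).

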