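---
title: "Selecting the number of muscle synergies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of muscle synergies: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Muscle synergy analysis factorizes multi-muscle surface EMG (sEMG) envelopes
`V` (muscles x time) as `V ~ W C`, with non-negative weight vectors `W`
(muscles x n, the time-invariant loading of each muscle on a synergy) and
non-negative activation coefficients `C` (n x time, the time-varying drive of
each synergy). The factorization needs the number of synergies `n` as an
input, and `n` itself has become a clinically interpreted quantity
(neuromuscular complexity). Most studies pick `n` by thresholding the
variance accounted for (VAF) of the reconstruction, which hinges on an
arbitrary cut-off. This package implements an alternative criterion —
ChoOSyn — built on two principles: synergies should be *consistent in time*
(stable across epochs of the same walk) and *mutually dissimilar* (an
information-rich, non-redundant base), together with the full extraction
pipeline and the three VAF baselines it is compared against.

## The extraction pipeline

For a walking trial with heel-strike events, the pipeline is:

1. **Segmentation and time normalization.** Each gait cycle (between
   consecutive heel strikes) is resampled to 1000 samples by linear
   interpolation. With k+1 events the walk yields k cycles; trailing
   samples after the last event are discarded. Linear interpolation is the
   simplest scheme that preserves monotone ramps; the cycle grid maps the
   source cycle `[e_i, e_{i+1})` affinely onto 1000 points, so a cycle that
   is already 1000 samples long passes through unchanged.
2. **Envelope extraction.** Per muscle, over the whole-walk concatenation:
   zero-phase 8th-order Butterworth high-pass at 35 Hz (movement artifacts,
   baseline wander), demeaning, full-wave rectification, zero-phase
   5th-order Butterworth low-pass at 12 Hz. We filter the concatenated walk
   rather than individual cycles so per-cycle edge transients do not
   accumulate, and we pad with an odd mirror image before the
   forward-backward pass to suppress start-up transients. Negative values
   produced by low-pass ringing are clipped to zero (the factorization
   needs non-negative input). The normalized timebase is treated as a
   nominal 1000 Hz axis (1 cycle ~ 1 s), so the 35/12 Hz cut-offs apply
   as printed; this is a substitution for an unstated native sampling
   rate, and the filter stage is applied after time normalization, in the
   pipeline's stated order.
3. **Amplitude normalization.** Each muscle is divided by its global
   maximum over the walk, putting every channel in [0, 1]. An all-zero
   channel is left untouched with a warning rather than divided by zero.
4. **Subgrouping.** Ten adjacent cycles are concatenated into one subgroup
   (muscles x 10,000); a walk with N cycles gives floor(N/10) subgroups,
   leftovers discarded. Subgroups are the "epochs" against which temporal
   consistency is judged.
5. **Factorization.** Every subgroup is factorized for each candidate
   order n = 1..8 by NMF with alternating non-negative least squares
   (ANLS): exact block-principal-pivoting NNLS solves for `C` given `W`
   and `W` given `C`, 5 random restarts (3 in the desk preset), up to 1000
   iterations. Stopping: relative Frobenius residual below 1e-6, *or*
   iteration-to-iteration progress of the RMS residual below 1e-6 (the
   classical alternating-least-squares termination on the residual error),
   *or* maximum relative change of the factor entries below 1e-6. On data
   that are not exactly low-rank the residual plateaus while the factors
   keep drifting microscopically, so the progress rule is the one that
   normally fires; without it every fit runs the full 1000 iterations for
   no measurable gain in the selection outcomes. The restart with the
   smallest residual is kept, and the scale indeterminacy is fixed by
   normalizing columns of `W` to unit Euclidean norm (compensated in `C`).
6. **Coefficient averaging and sorting.** The 10,000-sample coefficients
   are averaged across their ten 1000-sample windows, giving one mean
   activation per cycle. Because NMF returns synergies in arbitrary order,
   the weight columns of all subgroups are pooled and clustered with
   k-means under cosine distance (k = n, 15 restarts, up to 1e5
   iterations); within each subgroup, synergies are matched one-to-one to
   clusters by exhaustive optimal assignment (n <= 8, so at most 40,320
   permutations — exact and dependency-free). Centroid updates are
   arithmetic means of raw member vectors (cosine is scale-invariant, so
   centroids are not re-normalized); an emptied cluster is re-seeded with
   the point farthest from its centroid, never stealing a cluster's only
   member. Restart selection uses the lowest total within-cluster cosine
   distance.

## The ChoOSyn criterion

For each order n in 2..8 (similarity is undefined at n = 1), four
parameters are computed from the sorted stack:

* **ICVW, ICVC** — intra-cluster variability of weights and coefficients:
  for each synergy, the mean (across subgroups) cosine similarity between
  the subgroup vector and the cross-subgroup centroid; ICV is the worst
  case `max_i (1 - mean_j cos)`. 0 = perfectly repeatable, 1 = unstable.
* **WS** — weight similarity: the maximum pairwise cosine between weight
  centroids at that order (the two most redundant synergies).
* **CS** — coefficient similarity: the cosine between the two activation
  centroids produced by the split of one level-(n-1) synergy into two
  level-n synergies. The split pair is found by clustering the n level-n
  weight centroids into n-1 clusters initialized at the level-(n-1)
  centroids; the pigeonhole principle guarantees a multi-member cluster.
  For n = 2 the pair is trivially both synergies. If several clusters
  carry multiple members the pair with the highest CS is taken — the same
  worst-case philosophy as WS.

These combine as `ChoOSynW(n) = WS(n) + ICVW(n)` and
`ChoOSynC(n) = CS(n) + ICVC(n)`. Below the correct order both sums are low
and stable; above it, synergies become unstable and redundant, so the
profiles jump.

**Step and local-minimum detection.** The profiles are screened with
signed first differences `d(n) = value(n+1) - value(n)` and the threshold
`theta = mean(|d|)`. A *step* sits at n when `d(n) > theta` and the
preceding difference is stable (`|d(n-1)| <= theta`, or n = 2); the
candidate is the level *before* the sharp rise. A *local minimum* sits at
n when `-d(n-1) > theta` and `d(n) > theta`. Only the two highest
candidate orders per profile are kept. The source procedure defines steps
and minima in prose; this formalization is ours, and three choices in it
deserve a note: differences are signed (the prose needs direction — "an
abrupt decrease followed by an abrupt increase"), the stability
requirement applies only to the preceding difference (requiring following
stability too would erase steps at the right edge of the profile), and a
perfectly flat profile yields no candidates.

**Final rule.** If the W-side and C-side candidate sets intersect, the
common order wins (two common orders: the smaller
`ChoOSynW + ChoOSynC`; an exact tie: the smaller n). Otherwise, the order
minimizing `ChoOSynW(n) + ChoOSynC(n)` over the union of candidates is
chosen. If both candidate sets are empty — possible on degenerate,
flat profiles — the minimizer over all orders is returned and flagged as a
fallback in the diagnostics. Tie-breaks and the empty-candidate fallback
are our additions; the source never addresses them.

## VAF baselines

VAF is the uncentered reconstruction quality
`(1 - sum((M - R)^2) / sum(M^2)) * 100`, computed per (subgroup, order) and
averaged across subgroups per order (the aggregation is unstated in the
source; averaging per subgroup keeps the curve consistent with the
factorizations actually performed).

* **T-VAF** — smallest n with VAF at or above a threshold (90% and 95%
  variants).
* **E-VAF** — the elbow: the interior order at maximum perpendicular
  distance from the chord joining the curve's endpoints. A discrete
  second-difference curvature estimate is dominated by flat-region noise
  on a percent-scale curve; the chord distance is the standard robust
  knee detector and matches the "highest curvature point" intent. A
  perfectly linear curve has no elbow and raises a degenerate-elbow
  condition.
* **P-VAF** — the plateau: the first order from which an ordinary
  least-squares line through the remaining points has mean-square error
  below 1e-2 *on the percent scale*. On the fraction scale the same
  threshold would be satisfied almost everywhere and the criterion would
  be vacuous; the percent-scale reading demands ~0.1% RMS residual, which
  is what a plateau looks like. At least three points are required per
  fit (a two-point fit has zero error identically and would always fire).

Failures (a threshold never crossed, a curve that never flattens) are
first-class outcomes: they count as incorrect classifications in the
benchmark's fraction correct but are excluded from ME/RMSE, with the
failure count reported separately.

## The pseudo-real sEMG simulator

Real recordings behind the original study are unavailable, so the
ground-truth sets are synthesized with the statistical structure the
pipeline assumes — low-rank, cycle-locked, non-negative — and the signal
model is the study's own: per muscle, the noiseless envelope (weights row
times coefficients) multiplies a zero-mean unit-variance Gaussian carrier,
and background noise of standard deviation `10^(-SNR/20)` is added
(`S = W_muscle x C x G_S + G_N`); the no-additive-noise condition omits
`G_N` entirely and is encoded as `snr_db = NA`, not as an infinite SNR.
Carrier and noise are i.i.d. across samples and muscles, with separate
seeds.

Ground-truth structure, and why each default looks the way it does:

* **Weights**: each synergy is dominated by its own subset of muscles
  (loadings 0.6–1) with small background loadings elsewhere (0.01–0.08) —
  walking synergies are modular. Draws whose weight columns exceed a
  pairwise cosine of 0.6 are rejected and redrawn (the distinctness cap);
  generation fails after 60 rejected draws.
* **Activations**: per cycle, a Gaussian burst with a stratified centre —
  synergy s of n peaks inside phase `[(s-1)/n, s/n]` — because gait
  synergies tile the cycle (weight acceptance, push-off, swing, ...).
  Burst width scales with the inter-burst interval (sigma 0.08–0.18 of
  cycle/n; more synergies, narrower phases), centres jitter cycle-to-cycle
  with sd 2% of the cycle and amplitudes by 5%, and a synergy carries a
  smaller secondary burst with probability 0.15. Bursts wrap around the
  cycle boundary.
* **Scaling**: per-synergy signal power is balanced — every rank-1
  contribution `outer(w_s, c_s)` gets the same Frobenius norm, applied as
  a column scaling of `W` so the distinctness geometry is untouched —
  and one global scalar puts the strongest muscle envelope peak at 1.
  Balanced power encodes the view that each synergy drives its phase of
  the cycle with comparable intensity; without it the weakest synergy is
  nearly free to absorb into the others and *no* order-selection criterion
  (including the VAF baselines) can recover the true order reliably, which
  contradicts the study design this simulator stands in for.

What the simulator deliberately does **not** model: motion artifacts,
electrode crosstalk, non-Gaussian EMG statistics, inter-muscle noise
correlation, or cadence variability (cycles are generated directly on the
normalized 1000-sample timebase, so segmentation is an identity-like
resample). Passing benchmarks on these data therefore show that the
criteria recover a known low-rank structure through the full pipeline
under carrier and background noise — not that they survive every artifact
of real electrode recordings.

A walk's events are its heel strikes: k+1 strikes delimit k cycles, so a
recording simulated with `n_cycles = 31` provides 30 analysable cycles
(3 subgroups). The benchmark presets account for this off-by-one
explicitly.

## The benchmark

`build_simulated_dataset()` lays out the full study grid lazily — three
true orders (4, 5, 6), five ground-truth subjects each, augmented to 25
sets per level by crossing every subject's weights with every subject's
coefficients, times five noise conditions (no additive noise, 30, 25, 20,
15 dB) = 375 recordings — as a manifest of seeds; signals are synthesized
on demand, so the grid costs megabytes, not gigabytes. Scoring per method
and condition: fraction of correctly classified sets, mean error
(selected minus true, signed) and RMSE, with failed selections counted
against the fraction and excluded from the error metrics.

**Problem sizes used in this package's own checks** (chosen once as the
package's working scale): the acceptance script and the heavyweight tests
use the desk preset — 30 analysable cycles per set (3 subgroups), 3 NMF
restarts — with the full 75-set grid for the no-additive-noise condition,
and a 27-set-per-condition grid (3 subjects per level) for the 25/15 dB
noise-robustness checks. The full-scale protocol (150 cycles, 15
subgroups, 5 restarts) is exposed through the same functions and differs
only in cost.

## Numerical choices and degenerate inputs

* NNLS is solved on the normal equations by block principal pivoting with
  a feasibility tolerance scaled to the problem (`1e-9 x max |A'B|`);
  singular passive blocks fall back to a pseudo-inverse solve.
* ANLS restart r uses seed `seed + r`; extraction derives per-(subgroup,
  order) seeds from one master seed, and the whole benchmark is a pure
  function of its manifest and master seed.
* Cosine similarity is undefined for zero-norm vectors and raises a typed
  error; an all-zero weight column at sorting time aborts that set's
  ChoOSyn branch (the benchmark records the failure and the VAF branches
  continue).
* Interpolation at segment boundaries uses the cycle-end sample as the
  right interpolation node, so downsampled cycles never extrapolate.
* Events are 1-based sample indices inside R, 0-based in the interchange
  text format.

## Known limitations

* The ChoOSyn step/minimum formalization is one reading of a procedure
  stated in prose; the candidate tags and fallback flag are exposed in
  the selection diagnostics so a user can audit every decision.
* Filtering after time normalization distorts the physical frequency axis
  whenever the cadence is not one cycle per second; the cut-offs are
  nominal. This mirrors the pipeline's stated order but is worth knowing
  when applying the package to real recordings with unusual cadence.
* The simulator's realism boundaries above; in particular, results on
  simulated data transfer to real sEMG only to the extent that real
  synergies are as modular and power-balanced as the generator assumes.
  One concrete consequence: on these synthetic sets the selection criteria
  remain essentially perfect down to 15 dB SNR, because additive noise
  enters the recovered envelopes mainly as a shared baseline that leaves
  the VAF knee and the ChoOSyn step intact. Real recordings, whose
  synergies overlap more and whose powers are less balanced, lose accuracy
  at low SNR well before these synthetic ones do — simulated noise
  robustness is an upper bound, not a forecast.
* `m > 16` muscles would exceed the NNLS solver's stack-buffer bound for
  the *order* dimension only if more than 16 synergies were requested;
  orders are capped at 8 throughout.
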