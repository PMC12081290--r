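---
title: "Methods: detecting and characterizing schema cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing schema cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the analysis model implemented by `schemacells`,
the assumptions behind it, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not establish about real
recordings.

## The task model

The dual figure-of-eight odor-sequence task presents ten odors in two
fixed sequences ("mazes"), each decomposed into two subsequences (a, b) of
four positions P1–P4. Positions P1 and P2 are nonrewarded, P3 and P4
rewarded, and one rewarded odor repeats within subsequence a. A session is
320 trials in four alternating 80-trial blocks (one of the two alternation
orders, chosen at random per session). Each trial progresses through light
onset, nose poke, odor delivery, unpoke, and either a go response (well
entry, then outcome after a 0.4–1.5-s delay) or a no-go (trial terminates
after a 2-s window); the intertrial interval is 4 s after correct trials
and 6 s after errors.

The eight trial types of a maze are the (subsequence, position) pairs. We
pin their order as subsequence a P1–P4 then b P1–P4 throughout. No
ordering is canonical for the 72-element profiles; any fixed order gives
identical cross-maze correlations as long as both mazes use the same one,
so one is pinned purely for reproducibility.

## Epoch rates

Nine 500-ms epochs are anchored to trial events: ITIa (the 500 ms before
light onset), light, poke, odor, unpoke, choice (well entry), outcome
(reward delivery), and postout and ITIb (the two 500-ms windows following
the end of the outcome period). On no-go trials, where well entry and
outcome are absent, the choice epoch anchors to trial termination and the
outcome epoch to 500 ms after termination, so the four late epochs tile
the two seconds after the trial ends. All windows are half-open
`[t, t + 0.5 s)`; timestamps are seconds.

Rates are computed as Gaussian-smoothed spike mass in the window divided
by the 500-ms duration, the continuous equivalent of counting in 100-ms
bins and smoothing with a σ = 50 ms kernel. Two details are deliberate:

* **Traces vs. epoch mass.** For displayed traces
  (`smooth_binned_rate()`), kernel mass is truncated at the analysis
  window and renormalized, so a trace integrates exactly to its spike
  count and no spikes are fabricated outside the trial. For epoch rates
  the mass is *not* renormalized: leakage across epoch boundaries is
  symmetric and averages out for locally stationary firing. Whether the
  original analysis summed mass or averaged smoothed bins differs only in
  these edge effects; both are available (`smooth = TRUE/FALSE` exposes
  raw counts for oracle tests).
* **Exclusions.** Trials without a nose poke lack anchors for most
  epochs and are excluded from rate matrices. Error trials are included
  when their epochs are resolvable; a correct-trials-only restriction is
  a matter of subsetting the trial table before matrix construction.

A full session yields a 160 × 9 matrix per maze per unit (8 types × 20
trials), and type-averaging gives the 72-element profile.

## Classification and attribution

A unit is a **schema cell** when the Pearson correlation of its two
72-element profiles exceeds 0.8 with p < 0.01 (two-sided t transform,
70 df — the analysis names only the significance level, so the exact
small-sample test is used), **nonschema** for 0.4 ≤ r ≤ 0.8, and
**noncoding** below 0.4 or when a profile is degenerate (zero variance,
e.g. a silent unit).

Attribution asks which factors the generalized profile depends on. For
each factor, both mazes' trial matrices are shuffled 1,000 times within
strata that destroy only that factor, profiles are rebuilt and r
recomputed, and the factor is flagged when the observed r strictly
exceeds the 990th order statistic of the 1,000 shuffled values (a literal
"greater than 99%" reading, conservative on ties; a 1e-12 guard keeps
exact ties from rounding into flags). The three shuffles:

* **Epoch** — the nine values of every trial row are permuted uniformly,
  independently per trial. Trial-level (reward, position) marginals are
  untouched.
* **Reward** — within each epoch × subsequence, each nonrewarded cell is
  paired with the rewarded cell of the same within-category ordinal and
  within-type trial index (P1 ↔ P3, P2 ↔ P4) and the pair is swapped with
  probability 1/2, independently per epoch. This is the only exchange
  that alters the reward relationship while leaving epoch and position
  within subsequence intact: because reward is a deterministic function
  of position in this task, any unconstrained permutation across the
  reward boundary would destroy position structure too and attribute
  position tuning to reward. Pairwise exchange is therefore used instead
  of a free within-stratum permutation.
* **Position** — values are permuted uniformly across positions (and
  subsequences) within each epoch × reward category, destroying position
  contrasts while preserving epoch and reward relationships.

All three preserve per-stratum value multisets, and hence the grand mean,
exactly. Under a flat (null) unit each shuffle is exchangeable with the
data, so the flag rate per factor is ≈ 1% by construction of the 99% cut;
this calibration is tested on 500 simulated null units.

The selectivity ANOVA (epoch, 9 levels; reward, 2; position, 4 pooling
subsequences) faces the same aliasing: reward is a linear function of the
position dummies, so a crossed main-effects model is rank deficient. The
implemented decomposition is sequential — epoch, then reward, then
position within reward (2 residual df) — which mirrors how the shuffles
separate "reward" from "position independent of reward". On the balanced
task design the epoch sum of squares is order invariant. Partial
η² = SS_factor / (SS_factor + SS_error); the preferred level of a
significant factor is the argmax of its mean rates, ties broken toward
the lowest-index level.

## Decoding

The trial-type decoder is an L2-regularized linear multiclass model:
one-vs-rest ridge regression on class indicators with argmax aggregation,
fixed regularization strength λ = 1, and per-feature standardization
fitted on the training fold only. The original analysis names the family
(linear multiclass classification / linear SVMs) but no hyperparameters;
closed-form ridge keeps the 1,000-repeat leave-out loops fast and its
accuracy is calibrated at chance (12.5%) on flat units. Indicator
regression can mask interior classes when class means are nearly
collinear; this does not arise for the rate geometries produced by the
task, and the chance and separability tests guard the regime the package
uses. One caveat is recorded for users substituting their own features.

Single-cell mode holds out one random trial per type from maze 1 (8 × 9
test set), trains on the remaining 152 × 9, and tests within maze and on
the maze-2 trials with identical within-type indices. Ensemble mode
builds a pseudo-ensemble across units that were not recorded together by
aligning trials on (type, within-type index) — a modeling assumption, not
a property of the data — draws 15 trials per type (120 × 9 per maze),
leaves one per type out, and trains per epoch with the epoch's rate
across units as features, 200 repeats. Chance is 1/8 throughout, verified
by a label-permutation null.

## Population geometry

Condition responses (or trials) are embedded jointly into three
dimensions by PCA or Isomap (19 neighbors, one less than the 20
repetitions of a condition) and the two mazes' point sets are compared by
symmetric Procrustes distance: both configurations centered and scaled to
unit total scatter before the optimal rotation, so the statistic is
symmetric, zero exactly on the similarity orbit, and comparable across
populations (the original states no normalization; the symmetric form is
the standard choice). Canonical-variable clustering reduces trials to 30
PC scores, extracts discriminant axes (the canonical variables of a
MANOVA on those scores), and scores separation by silhouettes on the
first two axes. The tensor analysis fits a non-negative CP decomposition
(units × epochs × trials) by multiplicative updates with 10 random
restarts by default — the objective is nonconvex, and restarts are what
make the rank-nesting property (error at rank 8 ≤ rank 6) hold in
practice. Components are reported with unit-norm unit/epoch factors and
scale pushed into the trial factors.

## The synthetic-session generator

The generator is the package's test bed and defines its study conditions:
320-trial sessions (4 × 80 alternating blocks), 20 trials per type (40
for recovery tests), nine epochs, and Poisson units. A unit's expected
rate for (maze, type, epoch) is

λ_m(t, e) = γ · S(t, e) + (1 − γ) · M_m(t, e),

with S a shared multiplicative profile (baseline × epoch gain × position
gain × reward gain), M_m independent per-maze profiles, and γ the
maze-generalization parameter. Spikes are Poisson counts per epoch window
placed uniformly, with baseline-rate firing between windows — sufficient
for epoch-level analyses, which never read sub-epoch structure. Latencies
are log-normal (positive, right-skewed); accuracies default to 0.95/0.98
per position, representative of well-trained performance. Where two
windows overlap (reward delays under 500 ms put the outcome window inside
the choice window's tail) the later-starting window owns the overlap, so
realized choice-epoch rates on short-delay trials mix in the outcome
rate; convergence tests therefore fix the delay range at 0.5–1.5 s while
the default remains 0.4–1.5 s.

Category mixes draw schema-like units (γ = 1, strong gamma-distributed
gains), nonschema-like units (γ = 0.5 by default, giving expected
cross-maze r ≈ 0.5, inside the nonschema band), and noncoding-like flat
units. What passing recovery tests show is that the classifier separates
these regimes at realistic firing rates and trial counts; what they do
not show is robustness to features of real data the generator omits —
non-Poisson variability and slow rate drift, correlated noise across
units, behavioral covariates of firing, electrode instability, and
learning within session. Conclusions about real recordings rest on the
method, not on these simulations.

## Numerical and reproducibility notes

* All generation and resampling is a pure function of explicit seeds;
  the pipeline fans a global seed into independent per-stage seeds, and
  shuffle nulls run in compiled code drawing from R's RNG stream (an R
  reference implementation is kept and tested for agreement).
* Problem sizes used by the shipped checks: recovery at 200 units × 40
  trials/type per γ; attribution calibration at 500 null units × 1,000
  shuffles × 3 factors; decoder calibration at 1,000 (single-cell) and
  200 (ensemble) repeats.
* Degenerate inputs: zero-variance profiles classify as noncoding and
  leave attribution undefined (NA flags); silent units yield all-zero
  matrices; disconnected Isomap neighbor graphs and all-coincident
  Procrustes inputs raise informative errors; near-zero-variance PCs are
  dropped before discriminant analysis.
* The epoch-subset option (e.g. restricting to ITIa–odor, the part of
  the trial uncontaminated by responses and reward) reuses the same
  thresholds on the shorter profile; thresholds are not rescaled.

## Limitations

The package does not model spike sorting, continuous signals, behavioral
learning, or optogenetic dynamics, and it makes no attempt to reproduce
real-data prevalence figures, which require the original recordings. The
ensemble decoder's trial-alignment convention and the symmetric
Procrustes normalization are documented choices where the source analysis
is silent; both are isolated behind small functions and easy to swap.
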