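---
title: "Complexity and causality of cardiovascular variability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and causality of cardiovascular variability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvcausal)
```

## The problem

Beat-to-beat series of heart period (HP, ms), systolic arterial pressure
(SAP, mmHg) and respiration (RESP, a.u.) are jointly shaped by a small set
of regulatory mechanisms — the cardiac baroreflex (SAP→HP), the coupling of
respiration to vagal outflow (RESP→HP), the mechanical feedforward pathway
(HP→SAP) and the intrathoracic-pressure transfer (RESP→SAP). `cvcausal`
quantifies (i) the *complexity* of each series, defined as its degree of
unpredictability given the whole universe Ω of recorded series, and (ii)
the *strength of each directed link*, defined as the predictability lost
when the candidate cause is removed from Ω. The second definition is
Granger's: a cause is a series carrying unique information about the future
of the effect.

All indexes are built on one object, the non-uniform multivariate embedding

$$Z_i(n) = [\,y_j(n-k) : \tau_j^i \le k \le p_i,\ 1 \le j \le M\,],$$

whose candidate components are individual (source, lag) pairs. The minimum
delays encode physiology: SAP and RESP may act on HP *within* the same beat
(τ = 0, the fast vagal reflex and respiratory gating), RESP on SAP within
the beat (intrathoracic pressure), while HP cannot affect the SAP of its own
beat by construction of the measurement (τ = 1), and HP/SAP act on RESP only
with delay (τ = 1). Self delays are always ≥ 1. The grid size is
$q_i = \sum_j (p_i - \tau_j^i + 1)$; with the default p = 8 the HP effect
has 8 + 9 + 9 = 26 candidates. (A description of the candidate set as
"8 components per series" is common; we use the exact grid arithmetic
above, so τ = 0 sources contribute p + 1 components.)

## The three estimators

**MB (linear model-based).** The effect is regressed by ordinary least
squares, with no intercept (series are zero-mean by construction), on the
full grid at order p; the in-sample mean square prediction error λ²(p) of
the unit-variance effect is tracked over p = 1…8. Because in-sample λ² is
(essentially) non-increasing in p, the order is chosen at the minimum of
the Akaike figure of merit

$$\mathrm{AIC}(p) = (N-p)\,\ln \lambda^2(p) + 2\,q(p),$$

with q(p) the number of estimated coefficients. NCI^MB = λ²(p°), clipped to
[0, 1]. The causality ratio re-fits at the *same* order and over the *same*
target rows with the cause's columns removed; in-sample nesting then
guarantees CR^MB ≤ 0, which the test suite asserts to 1e−10.

**LP (model-free local predictability).** Prediction is the zero-order
k-nearest-neighbor predictor: the inverse-distance weighted mean of the
images of the k rows closest to Z_i(n) under the maximum norm, with a
temporal (Theiler) exclusion |m − n| ≤ T. The embedding is grown greedily:
every remaining candidate is appended tentatively, scored by the squared
correlation r² between the series and its leave-self-out prediction over
all rows, and the best one retained; after selecting (source s, lag l) all
candidates of s with lag ≤ l are pruned, so per-source lags strictly
increase. Selection runs until the candidate set is empty; the r² profile
typically rises and then falls (sparsity), and NCI^LP = 1 − max r² at the
peak dimension q°.

**CE (model-free conditional entropy).** Same construction, different
functional: the per-row conditional distribution of the effect is the set
of images of the k nearest neighbors, its Shannon entropy is the negative
log of the fraction of unordered distinct image pairs within a tolerance ε,
and CE is the average over rows. The greedy criterion is the *minimum* of
CE; NCI^CE = min CE / SE, where SE is the same estimator with an empty
conditioning set (to which `conditionalEntropy()` reduces exactly at q = 0).

For both model-free ratios the reduced index re-evaluates the *optimal
selected set minus the cause's components*, with no re-selection; when the
optimal embedding holds no cause component the ratio is exactly zero.

## Parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| window length | 256 | beats | the conventional short-term span; long enough for k = 30 neighborhoods, short enough for approximate stationarity |
| maximal lag p | 8 | beats | covers baroreflex and respiratory latencies at normal heart rates |
| orders searched (MB) | 1–8 | — | same span as the MF candidate grids |
| neighbors k | 30 | — | the standard operating point of both MF estimators at N = 256 |
| tolerance ε | 0.1·(P84 − P16) of the effect | normalized units | ≈ 0.2 for Gaussian data (the 84–16 span is ≈ 2 SD); computed once on the full normalized window and reused for every conditional sample, since ε is a property of the effect, not of a neighborhood |
| Theiler half-width T | p | beats | the value is not standardized in the field; matching the embedding span removes all trivially overlapping vectors. It is exposed as `theiler` and should be treated as a sensitivity parameter |
| significance α | 0.05 | — | conventional |

## Preprocessing

Per subject, a window of 256 consecutive beats is drawn uniformly at
random. A candidate window is accepted when, after linear detrending, its
two halves agree in mean within 0.5 pooled SD and in variance within a
factor 2 — an automatic stand-in for the visual screen against slow mean
drift and sudden variance changes. After `maxTries` (default 100) failed
draws the best-scoring window is returned with a warning. Within the
window each series is linearly detrended and then normalized to zero mean
and unit *population* variance (the NCI is a variance ratio, so the
convention cancels, but one must be fixed for exact tests). Normalization
happens inside the selected window, not on the full record, because the
indexes must describe the analyzed segment. Baroreflex and traditional
indexes (µ, σ², BRS, BEI) are computed on the raw-unit window *before*
normalization: their thresholds are in ms and mmHg.

## Baroreflex sequence method

A SAP ramp is a 4-beat window with three consecutive same-sign SAP changes,
|ΔSAP| > 1 mmHg and |correlation against the beat index| > 0.85 (the
absolute value makes descending ramps, whose correlation is negative,
eligible). A baroreflex sequence additionally requires concordant HP
changes, |ΔHP| > 5 ms and correlation > 0.85 in the [SAP, HP] plane
(concordance makes it positive). All inequalities are strict; overlapping
windows are each counted, and a long monotone run therefore contributes one
ramp per window — the common sliding-window convention. BRS is the
unweighted mean of the per-sequence regression slopes (ms/mmHg); BEI is the
sequence-to-ramp count ratio. With no sequence or no ramp the result is
`NA`, never zero: an absent reflex response and a zero-gain response are
different findings.

## Numerical choices and degenerate inputs

* **Ties.** Neighbor ties at equal max-norm distance resolve to the smaller
  row index; candidate ties in the greedy selection resolve to the earlier
  candidate in canonical order (sources in universe order, lags ascending).
  Both rules make runs bit-reproducible.
* **Zero distances.** An exact embedding match dominates the inverse-
  distance weights in the limit, so the prediction is the plain mean of the
  zero-distance images.
* **Zero pair counts.** The within-ε pair probability is floored at one
  pair out of k(k−1)/2 (or n(n−1)/2 unconditionally), keeping every entropy
  finite; pair counting uses unordered distinct pairs with a closed
  inequality (≤ ε), self-pairs excluded.
* **λ² floor.** ln λ² uses a 1e−12 floor so noiseless toy inputs select
  the perfectly fitting order immediately.
* **Constant series** cannot be normalized, have no defined r² as an
  observed series, and zero Shannon entropy — all are rejected with typed
  degenerate-input errors. A constant *prediction* scores r² = 0 (no
  predictive information), and an empty embedding scores r² = 0 / CE = SE.
* **Clipping.** NCIs are clipped to [0, 1]; clipping is monotone, so the
  MB nesting inequality survives it.

## Open design points, and how they were settled

* **Form of the causality ratio.** The ratio is the *fractional*
  unpredictability decrement, normalized by the reduced-universe NCI; an
  absolute-difference variant is available via `form = "absolute"` on all
  three `cr*()` functions.
* **r² at selection time.** The k-NN prediction excludes the query row via
  the temporal window (leave-self-out), so the score is not inflated by
  each point predicting itself.
* **MB dimension in parsimony comparisons.** The number of components the
  MB approach actually uses at order p° is the full grid size q(p°) =
  Σ_j (p° − τ_j + 1) — every order increment adds one lag per source — and
  that is the quantity compared against the model-free q° when checking the
  parsimony ordering CE ≤ LP ≤ MB.
* **Per-point conditional sample.** The query's own image is excluded via
  the temporal window; pair probabilities use unordered distinct pairs (no
  Grassberger-style self-pairs).

## The synthetic generator

`simulateCoupled()` generates M series from stable linear autoregressions
with i.i.d. Gaussian innovations plus directed links: linear gains at any
lag (lag-0 links are generated in a topological order of the within-beat
graph and must be acyclic), and quadratic links gain·source² that are
invisible to linear analysis (a Gaussian source is uncorrelated with its
square) — the device used to demonstrate the model-free advantage. A weak
linear drift (default 0.1 SD over the record) emulates the slow
nonstationarity of real recordings and is removed by the detrending step.
Gaussian innovations make the MB residual variance analytic, e.g. a
unit-variance AR(1) with coefficient a has NCI^MB → 1 − a².
`simulateTrivariate()` fixes the study-like defaults: 256 beats, HP/SAP/RESP
labels, lag-0 links SAP→HP, RESP→HP, RESP→SAP, a lag-1 link HP→SAP, and an
oscillatory AR(2) respiration.

What the generator does **not** emulate: non-Gaussian and asymmetric beat
distributions, ectopic beats and measurement artifacts, closed-loop
baroreflex dynamics with realistic gains, and multi-scale rhythms beyond a
single AR(2) oscillation. Tests passing on this generator show estimator
correctness and recovery power under known ground truth; they do not certify
physiological validity on real recordings.

`simulateBaroreflexToy()` is fully deterministic: ramps are exact 1.5 mmHg
staircases (within-ramp correlation exactly 1) and effective ramps carry HP
responses of exact slope, while filler beats alternate in sign with
sub-threshold steps so they can never complete a ramp or sequence — the
detector counts provably equal the constructed ground truth, and BEI equals
the requested fraction exactly.

## Cohort stage

Across subjects, any computed index is associated with a covariate (age in
the motivating design) by Pearson correlation when the index passes a
normality gate and Spearman rank correlation otherwise. The gate is the
Lilliefors-corrected Kolmogorov–Smirnov test: mean and variance are
estimated from the sample, and the plain KS test against a fixed Gaussian
would be miscalibrated in that setting. Significance is two-sided at
α = 0.05 with no multiple-testing correction across the index family — the
tables are descriptive, mirroring the usual reporting practice.

## Problem sizes used in the test suite

Convergence checks run at the sizes where their analytic limits are sharp:
N = 8192 for the AR(1) residual-variance limit, N = 4096 × 50 seeds for
linear causal recovery, N = 1024 × 50 seeds for the nonlinear (quadratic)
recovery contrast, 50 subjects at N = 256 for the parsimony ordering, and
1000 null replicates (n = 100) for the level of the association stage.
Oracle comparisons (normal equations, exhaustive neighbor scans, pair-loop
conditional entropy) run on instances up to N = 200 where exhaustive
computation is exact and cheap.

## Known limitations

* The LP and CE estimators need roughly N ≥ (2T + 1) + k rows; at the
  default window they are comfortable, but short windows with large p and
  k fail with an insufficient-data error rather than degrading silently.
* Classical AIC overfits the order with asymptotic probability ≈ 0.28 when
  six higher orders compete; this is a property of the figure of merit, not
  of the implementation.
* In-sample λ² is compared across orders whose row sets differ by the first
  p beats, so the "non-increasing" property holds up to an O(1/N) boundary
  term.
* The Theiler width and k remain user-set; no automatic rule is provided.
* CR magnitudes across methods are not on a common scale (variance ratio
  versus information ratio); only signs and within-method comparisons are
  meaningful.
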